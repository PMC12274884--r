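## SWC I/O. 7-column format: id type x y z radius parent, '#' comments.
## Type codes: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite.

swc_type_to_neurite <- c(`2` = "axon", `3` = "basal", `4` = "apical")
neurite_to_swc_type <- c(axon = 2L, basal = 3L, apical = 4L)

#' Read a neuron morphology from an SWC file
#'
#' Soma samples (type 1) are collapsed to a centre and radius: the centre is
#' the mean of the soma sample positions and the radius the mean of the soma
#' sample radii (1-point and 3-point conventions both round-trip). Type codes
#' 2/3/4 map to
#' axon/basal/apical trees; each tree is re-rooted at its first sample whose
#' parent is a soma sample (or -1).
#'
#' @param path path to an SWC file.
#' @param meta optional metadata list attached to the result.
#' @return a [neuron_morphology()].
#' @export
read_swc <- function(path, meta = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lines[keep]
  if (!length(rows)) stop("SWC file has no data rows: ", path)
  fields <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("malformed SWC row at line ", which(keep)[which(nf != 7L)[1]],
         " of ", path, " (expected 7 columns)")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop("malformed SWC row at line ",
         which(keep)[which(rowSums(is.na(m)) > 0)[1]], " of ", path)
  df <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5],
                   radius = m[, 6], parent = as.integer(m[, 7]))
  soma <- df[df$type == 1L, ]
  if (!nrow(soma)) stop("SWC file has no soma sample: ", path)
  # multiple somata = more than one soma root
  if (sum(soma$parent == -1L) > 1L)
    stop("multiple somata in SWC file: ", path)
  center <- c(mean(soma$x), mean(soma$y), mean(soma$z))
  radius <- mean(soma$radius)
  soma_ids <- soma$id
  rest <- df[df$type != 1L, ]
  if (!all(rest$type %in% c(2L, 3L, 4L)))
    stop("unsupported SWC type code: ",
         paste(setdiff(unique(rest$type), 1:4), collapse = ", "))
  neurites <- list()
  if (nrow(rest)) {
    # tree roots: nodes whose parent is the soma or -1
    root_flag <- rest$parent %in% c(soma_ids, -1L)
    comp <- integer(nrow(rest))
    pidx <- match(rest$parent, rest$id)
    cur <- 0L
    for (i in seq_len(nrow(rest))) {
      if (root_flag[i]) { cur <- cur + 1L; comp[i] <- cur }
      else {
        if (is.na(pidx[i]))
          stop("node ", rest$id[i], " has unknown parent ", rest$parent[i])
        comp[i] <- comp[pidx[i]]
      }
    }
    for (k in seq_len(max(comp, 0L))) {
      sub <- rest[comp == k, ]
      ty <- swc_type_to_neurite[[as.character(sub$type[1])]]
      nodes <- data.frame(id = sub$id, parent = sub$parent,
                          x = sub$x, y = sub$y, z = sub$z,
                          diameter = 2 * sub$radius)
      nodes$parent[1] <- -1L
      neurites <- c(neurites, list(neurite_tree(nodes, ty)))
    }
  }
  neuron_morphology(center, radius, neurites, meta)
}

#' Write a neuron morphology to an SWC file
#'
#' Emits a 3-point soma (centre and two points offset by the radius along Y)
#' followed by the neurite trees with consecutive ids; roots attach to the
#' soma centre sample. Coordinates are printed with enough digits for
#' lossless round-trips at 1e-6 um.
#'
#' @param m a [neuron_morphology()].
#' @param path output path.
#' @export
write_swc <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC generated by dendronet", con)
  fmt <- function(id, type, x, y, z, r, parent)
    sprintf("%d %d %.9g %.9g %.9g %.9g %d", id, type, x, y, z, r, parent)
  sc <- m$soma_center; sr <- m$soma_radius
  out <- c(fmt(1L, 1L, sc[1], sc[2], sc[3], sr, -1L),
           fmt(2L, 1L, sc[1], sc[2] - sr, sc[3], sr, 1L),
           fmt(3L, 1L, sc[1], sc[2] + sr, sc[3], sr, 1L))
  next_id <- 4L
  for (tr in m$neurites) {
    nd <- tr$nodes
    new_ids <- seq.int(next_id, length.out = nrow(nd))
    pmap <- setNames(new_ids, nd$id)
    par <- ifelse(nd$parent == -1L, 1L, pmap[as.character(nd$parent)])
    ty <- neurite_to_swc_type[[tr$type]]
    out <- c(out, fmt(new_ids, rep(ty, nrow(nd)), nd$x, nd$y, nd$z,
                      nd$diameter / 2, as.integer(par)))
    next_id <- next_id + nrow(nd)
  }
  writeLines(out, con)
  invisible(path)
}

#' Write a population as an SWC directory with a JSON manifest
#'
#' @param population list of [neuron_morphology()].
#' @param dir output directory (created if needed).
#' @export
write_swc_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(population))
  for (i in seq_along(population)) {
    files[i] <- sprintf("neuron_%04d.swc", i)
    write_swc(population[[i]], file.path(dir, files[i]))
  }
  manifest <- lapply(seq_along(population), function(i)
    c(list(file = files[i]), population[[i]]$meta))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
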