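{
  "version": "1.0",
  "note": "Layer 2/3 temporal cortex parameters. Units: densities per mm^3, linear densities per um, thickness um. The mouse excitatory fraction is reported as 0.85 (methods) while results quote a 12% interneuron share; both are stored, and they are used as printed rather than forced to sum to 1.",
  "human": {
    "neuron_density": 25700,
    "excitatory_fraction": 0.70,
    "inhibitory_fraction": 0.30,
    "layer_thickness": 1070,
    "synapse_volume_density": 1.18e9,
    "synapse_linear_density": 0.88,
    "synapses_per_neuron": 15000,
    "synapses_per_connection": 4,
    "column_n_pc": 10500,
    "column_n_in": 4500,
    "column_n_pc_results": 10621,
    "column_n_in_results": 4503
  },
  "mouse": {
    "neuron_density": 137600,
    "excitatory_fraction": 0.85,
    "inhibitory_fraction": 0.12,
    "layer_thickness": 235,
    "synapse_volume_density": 2.656e9,
    "synapse_linear_density": 2.15,
    "synapses_per_neuron": 12000,
    "synapses_per_connection": 3.2,
    "column_n_pc": 15200,
    "column_n_in": 2700,
    "column_n_pc_results": 14377,
    "column_n_in_results": 2724
  },
  "shared": {
    "hex_side_length": 476,
    "apposition_threshold": 2,
    "target_network_density": 0.04
  }
}
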