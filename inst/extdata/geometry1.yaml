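# Square 20 x 20 x 1 cm blood chamber (no fillets)
fillet_radius: 0
chamber_length: 20
chamber_width: 20
chamber_height: 1
plexiglass_thickness: 1.1
tube_inner_diameter: 1.27
tube_outer_diameter: 1.31
tube_height: 1.4
port_inset: 1.2
port_scaling_factor: 0.3
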