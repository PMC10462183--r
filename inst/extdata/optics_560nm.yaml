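# Example SAIM optical configuration for the 560 nm laser line.
# Indices are literature values (aqueous buffer, thermal SiO2, crystalline
# silicon); replace with values measured for your chips and media.
wavelength_nm: 560
d_oxide_nm: 1900
n_buffer: 1.338
n_oxide: 1.46
n_silicon: {re: 4.05, im: 0.044}
chips:
  example_chip_A: {d_oxide_nm: 1894.2}
  example_chip_B: {d_oxide_nm: 1906.8}
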