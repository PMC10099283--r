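# Device waveguide stack, scaled to wavelength dimensions for modal
# analysis (the physical guide is mm-thick and is handled by the ray
# tracer). Indices from the device report; heights in micrometres.
n0: 1
n1: 1.41
n2: 1.40
n3: 1.39
n4: 1.38
n5: 1
heights_um: [2, 2, 2, 2]
wavelength_um: 0.55
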