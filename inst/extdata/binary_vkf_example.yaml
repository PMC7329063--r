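# example filter configuration (see read_filter_config)
variant: binary_vkf
lambda: 0.1
v0: 0.1
omega: 0.1
m0: 0
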