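# Example light-program configuration for the command-line interface:
# a 6 h light / 18 h dark cycle of mixed red+blue light.
mode: photoperiod
photoperiod: 6L18D
red: 26.62
blue: 26.62
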