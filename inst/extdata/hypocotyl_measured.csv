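# Published mean measured hypocotyl lengths (mm) of wild-type Arabidopsis
# (Col-4) seedlings after 10 days, by light quality and photoperiod
# (per-channel intensity 26.6 umol m-2 s-1; n = 10 seedlings per condition).
quality,photoperiod,length
blue,6L18D,5.13
red,6L18D,7.01
mixed,6L18D,5.59
blue,4L20D,6.14
red,4L20D,9.42
mixed,4L20D,6.95
blue,2L22D,8.77
red,2L22D,10.60
mixed,2L22D,9.20
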