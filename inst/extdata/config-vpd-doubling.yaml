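# Instantaneous VPD doubling (1 -> 2 kPa) under reference temperate growth
# conditions; all physiological constants at package defaults.
scenario: vpd_doubling
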