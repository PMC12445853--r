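# Instantaneous CO2 doubling (400 -> 800 ppm) under reference temperate
# growth conditions; all physiological constants at package defaults.
scenario: co2_doubling
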