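# measurement calendar, days after sowing
drought M1 29
drought M2 34
drought M3 37
drought M4 42
well_watered M1 29
well_watered M2 35
well_watered M3 38
well_watered M4 42
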