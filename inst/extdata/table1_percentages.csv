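label,numerator,denominator,printed_pct
success_women,73,143,51.0
ce_successful_women,34,73,46.6
laa_successful_women,19,73,26.0
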