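environment,rainfall_mm
2017,504.1
2018,228.0
2019,538.2
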