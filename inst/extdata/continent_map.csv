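country,continent
US,North America
CA,North America
GB,Europe
NL,Europe
DE,Europe
FR,Europe
SE,Europe
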