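# YAML writer at full numeric precision (the default truncates to 8
# significant digits, which breaks round-trip fidelity)
write_yaml_full <- function(x, path) yaml::write_yaml(x, path, precision = 15)
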