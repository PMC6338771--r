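# shared fixtures built once per test run
PARAMS <- thermo_params()
CONFIG <- scoring_config()
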