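state,zone
MA,America/New_York
NY,America/New_York
PA,America/New_York
GA,America/New_York
OH,America/New_York
FL,America/New_York
FL,America/Chicago
MN,America/Chicago
IL,America/Chicago
MO,America/Chicago
TX,America/Chicago
TX,America/Denver
CO,America/Denver
AZ,America/Phoenix
NV,America/Los_Angeles
CA,America/Los_Angeles
OR,America/Los_Angeles
OR,America/Boise
WA,America/Los_Angeles
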