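format-version: 1.2
default-namespace: biological_process

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0050896
name: response to stimulus
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0006950
name: response to stress
namespace: biological_process
is_a: GO:0050896 ! response to stimulus

[Term]
id: GO:0009408
name: response to heat
namespace: biological_process
is_a: GO:0006950 ! response to stress

[Term]
id: GO:0006979
name: response to oxidative stress
namespace: biological_process
is_a: GO:0006950 ! response to stress
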