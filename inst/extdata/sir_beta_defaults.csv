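network,beta
karate,0.12
dolphin,0.14
lesmis,0.082
polbooks,0.083
football,0.093
usair97,0.022
mouse_kasthuri,0.023
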