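category	n_snps
total	5140908
wild	4321515
local	4491942
commercial	3746643
shared_all_three	2832649
unique_wild	135613
unique_local	222579
unique_commercial	195701
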