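metric	value
total_variable_sites	769597
indels_removed	125372
snps_retained	644225
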