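reaction_id	pathway
R_s	uptake
R_1	upper_branch
R_3	upper_branch
R_2	lower_branch
R_bio	drains
R_p	drains
R_m	drains
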