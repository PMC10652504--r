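consequence,nmd_predicted,last_exon_or_50nt_rule,affected_region_critical,exon_skip_inframe,strength,tag
nonsense,TRUE,NA,NA,NA,VS,PVS1.nmd_vs
nonsense,FALSE,NA,TRUE,NA,S,PVS1.escape_critical_s
nonsense,FALSE,NA,FALSE,NA,M,PVS1.escape_m
frameshift,TRUE,NA,NA,NA,VS,PVS1.nmd_vs
frameshift,FALSE,NA,TRUE,NA,S,PVS1.escape_critical_s
frameshift,FALSE,NA,FALSE,NA,M,PVS1.escape_m
canonical_splice,NA,NA,TRUE,TRUE,S,PVS1.exonskip_critical_s
canonical_splice,NA,NA,FALSE,TRUE,M,PVS1.exonskip_m
canonical_splice,TRUE,NA,NA,FALSE,VS,PVS1.nmd_vs
canonical_splice,FALSE,NA,TRUE,FALSE,S,PVS1.escape_critical_s
canonical_splice,FALSE,NA,FALSE,FALSE,M,PVS1.escape_m
initiation_codon,NA,NA,NA,NA,M,PVS1.initiation_m
single_multi_exon_deletion,TRUE,NA,NA,NA,VS,PVS1.nmd_vs
single_multi_exon_deletion,FALSE,NA,TRUE,NA,S,PVS1.escape_critical_s
single_multi_exon_deletion,FALSE,NA,FALSE,NA,M,PVS1.escape_m
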