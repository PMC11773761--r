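criterion,total_n,other_n,complex_n
c1_adult_phys_and_mental,74731,53204,21527
c2_child_problem,96853,75326,21527
c3_vulnerability,161264,139737,21527
homelessness,92,71,21
high_ae,2189,1472,717
substance_abuse,16089,11714,4375
lone_parent,59106,53661,5445
child_in_care,4528,,
deprived,53373,47001,6372
multi_service,96713,76912,19801
c4_top_spend,66698,45171,21527
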