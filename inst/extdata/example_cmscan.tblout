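#target name         accession query name           accession mdl mdl from   mdl to seq from   seq to strand trunc pass   gc  bias  score   E-value inc description of target
#------------------- --------- -------------------- --------- --- -------- -------- -------- -------- ------ ----- ---- ---- ----- ------ --------- --- ---------------------
TPP                  RF00059   contig_A             -          cm        1      105     1501     1600      +    no    1 0.48   0.0   58.1   2.1e-12 !   -
Cobalamin            RF00174   contig_A             -          cm        1      191     4210     4012      -    no    1 0.51   0.0   71.4   5.5e-16 !   -
FMN                  RF00050   contig_B             -          cm        1      140      812      950      +    no    1 0.46   0.0   64.0   8.9e-14 !   -
#
# Program:         cmscan
# Version:         1.1.5 (Sep 2023)
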