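# Default activity crosswalk: detailed ATUS-lexicon-style code prefixes ->
# eleven top-level categories. Longest matching prefix wins, so 4- and
# 6-digit entries override the 2-digit tier they sit under.
#
# This table is a reconstruction of the standard 400+ -> 11 recode:
# sleeping/naps -> sleep; other personal/grooming/health self-care ->
# personal_care; household activities -> housework; care of household and
# non-household children -> childcare; care of household and non-household
# adults (incl. eldercare) -> adult_care; work and work-related -> work;
# consumer purchases and grocery shopping -> shopping; television viewing
# -> tv; eating and drinking -> eating; residual socializing / leisure /
# sports / religious / volunteer / education / services / telephone /
# uncodeable time -> leisure; all travel -> travel. Substitute your own
# table via load_crosswalk(path) to use a different assignment.
pattern,category
01,personal_care
0101,sleep
02,housework
03,childcare
0304,adult_care
0305,adult_care
04,childcare
0404,adult_care
0405,adult_care
05,work
06,leisure
07,shopping
08,leisure
09,leisure
10,leisure
11,eating
12,leisure
120303,tv
120304,tv
13,leisure
14,leisure
15,leisure
16,leisure
17,leisure
18,travel
50,leisure
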