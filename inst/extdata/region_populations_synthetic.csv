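# SYNTHETIC stand-in for the per-region population register:
# reconstructed as (regional net emission x 1e6 / printed per-capita net),
# so per-capita recomputation checks arithmetic conventions only.
# The national total population used for country-level per-capita is the
# published 5503664 (31.12.2020), not the sum of this column.
code,region,population
1,Uusimaa,1712821
2,Southwest Finland,486667
4,Satakunta,214074
5,Kanta-Hame,170382
6,Pirkanmaa,529385
7,Paijat-Hame,206279
8,Kymenlaakso,161151
9,South Karelia,126089
10,South Savo,131860
11,North Savo,248779
12,North Karelia,163056
13,Central Finland,271000
14,South Ostrobothnia,192520
15,Ostrobothnia,176168
16,Central Ostrobothnia,67958
17,North Ostrobothnia,416400
18,Kainuu,71301
19,Lapland,180000
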