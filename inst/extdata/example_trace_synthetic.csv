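bin_low_um,bin_high_um,value,weighting,value_kind,sample_id,genotype,plant
1.3999999999999999,1.476413661983728,8.0999510635630071e-06,volume,percent,synthetic_demo,WT,1
1.476413661983728,1.5569980723515731,1.0425026214671571e-05,volume,percent,synthetic_demo,WT,1
1.5569980723515731,1.6419808755015655,2.403981550163668e-05,volume,percent,synthetic_demo,WT,1
1.6419808755015655,1.7316021409332243,4.0648863478011499e-05,volume,percent,synthetic_demo,WT,1
1.7316021409332243,1.8261150414243468,0.0001447506847975418,volume,percent,synthetic_demo,WT,1
1.8261150414243468,1.9257865682234911,0.00039914866517218691,volume,percent,synthetic_demo,WT,1
1.9257865682234911,2.0308982852785151,0.00063806161182575303,volume,percent,synthetic_demo,WT,1
2.0308982852785151,2.1417471246318045,0.0014256015377946459,volume,percent,synthetic_demo,WT,1
2.1417471246318045,2.2586462252291164,0.0025234461095264716,volume,percent,synthetic_demo,WT,1
2.2586462252291164,2.3819258175116027,0.0047277339171999761,volume,percent,synthetic_demo,WT,1
2.3819258175116027,2.511934156289922,0.0096550049142019884,volume,percent,synthetic_demo,WT,1
2.511934156289922,2.6490385045357221,0.014279669316379199,volume,percent,synthetic_demo,WT,1
2.6490385045357221,2.7936261708696315,0.026341228018333131,volume,percent,synthetic_demo,WT,1
2.7936261708696315,2.9461056036765809,0.04070874223588887,volume,percent,synthetic_demo,WT,1
2.9461056036765809,3.1069075449392298,0.065517336407600921,volume,percent,synthetic_demo,WT,1
3.1069075449392298,3.2764862470490019,0.10680978367519249,volume,percent,synthetic_demo,WT,1
3.2764862470490019,3.4553207560320995,0.1620876772152105,volume,percent,synthetic_demo,WT,1
3.4553207560320995,3.6439162648155259,0.21844321981084264,volume,percent,synthetic_demo,WT,1
3.6439162648155259,3.8428055403559709,0.31912717092064358,volume,percent,synthetic_demo,WT,1
3.8428055403559709,4.0525504286630847,0.44983499458086107,volume,percent,synthetic_demo,WT,1
4.0525504286630847,4.2737434419687093,0.58574409622735424,volume,percent,synthetic_demo,WT,1
4.2737434419687093,4.5070094325256891,0.72866433400325126,volume,percent,synthetic_demo,WT,1
4.5070094325256891,4.753007357764611,0.95935134610283135,volume,percent,synthetic_demo,WT,1
4.753007357764611,5.0124321417948954,1.1150642898859102,volume,percent,synthetic_demo,WT,1
5.0124321417948954,5.2860166385088165,1.3604592085290572,volume,percent,synthetic_demo,WT,1
5.2860166385088165,5.5745337018340857,1.5564881537089919,volume,percent,synthetic_demo,WT,1
5.5745337018340857,5.8787983689832641,1.7046090069236732,volume,percent,synthetic_demo,WT,1
5.8787983689832641,6.1996701628675357,1.8118007118314186,volume,percent,synthetic_demo,WT,1
6.1996701628675357,6.5380555201789381,1.8302468782458849,volume,percent,synthetic_demo,WT,1
6.5380555201789381,6.8949103520002248,1.8804891320470172,volume,percent,synthetic_demo,WT,1
6.8949103520002248,7.2712427441758347,1.8167110290677062,volume,percent,synthetic_demo,WT,1
7.2712427441758347,7.6681158050723246,1.6274910032380452,volume,percent,synthetic_demo,WT,1
7.6681158050723246,8.0866506687729558,1.504844246033205,volume,percent,synthetic_demo,WT,1
8.0866506687729558,8.5280296621901712,1.3511497220263273,volume,percent,synthetic_demo,WT,1
8.5280296621901712,8.9934996450428937,1.0850830469693464,volume,percent,synthetic_demo,WT,1
8.9934996450428937,9.4843755321336687,0.95842089991236956,volume,percent,synthetic_demo,WT,1
9.4843755321336687,10.002044007875954,0.71938656562205139,volume,percent,synthetic_demo,WT,1
10.002044007875954,10.547967443564676,0.61148251424844191,volume,percent,synthetic_demo,WT,1
10.547967443564676,11.123688028456046,0.4173158293204241,volume,percent,synthetic_demo,WT,1
11.123688028456046,11.73083212632668,0.33950559956128318,volume,percent,synthetic_demo,WT,1
11.73083212632668,12.371114869818809,0.29999776933188094,volume,percent,synthetic_demo,WT,1
12.371114869818809,13.046345005550391,0.19173761961032801,volume,percent,synthetic_demo,WT,1
13.046345005550391,13.758430003676979,0.25595791267735202,volume,percent,synthetic_demo,WT,1
13.758430003676979,14.509381446339665,0.35981010281973119,volume,percent,synthetic_demo,WT,1
14.509381446339665,15.301320710220788,0.52134319140575458,volume,percent,synthetic_demo,WT,1
15.301320710220788,16.136484959260379,0.63492408788917154,volume,percent,synthetic_demo,WT,1
16.136484959260379,17.017233464462123,1.0694064292827778,volume,percent,synthetic_demo,WT,1
17.017233464462123,17.946054268641831,1.6781576465017634,volume,percent,synthetic_demo,WT,1
17.946054268641831,18.925571214945862,2.1019281868256225,volume,percent,synthetic_demo,WT,1
18.925571214945862,19.95855135899432,3.1650074817377476,volume,percent,synthetic_demo,WT,1
19.95855135899432,21.04791278558795,3.8641810276769619,volume,percent,synthetic_demo,WT,1
21.04791278558795,22.19673285206002,5.1898171678582186,volume,percent,synthetic_demo,WT,1
22.19673285206002,23.408256881560323,5.7874905289277008,volume,percent,synthetic_demo,WT,1
23.408256881560323,24.68590733082878,5.383610059980529,volume,percent,synthetic_demo,WT,1
24.68590733082878,26.033293458357051,5.986597593299094,volume,percent,synthetic_demo,WT,1
26.033293458357051,27.454221520249984,6.7854101258065604,volume,percent,synthetic_demo,WT,1
27.454221520249984,28.952705522589103,5.6746046642939749,volume,percent,synthetic_demo,WT,1
28.952705522589103,30.532978560673058,6.6079796543996521,volume,percent,synthetic_demo,WT,1
30.532978560673058,32.199504777167128,6.0482880078808678,volume,percent,synthetic_demo,WT,1
32.199504777167128,33.95699197294276,4.1430806302970362,volume,percent,synthetic_demo,WT,1
33.95699197294276,35.810404906231781,3.4575174460907725,volume,percent,synthetic_demo,WT,1
35.810404906231781,37.764979317664086,2.4393306287190484,volume,percent,synthetic_demo,WT,1
37.764979317664086,39.826236720808716,2.011503511877029,volume,percent,synthetic_demo,WT,1
39.826236720808716,42,0.95526412802810579,volume,percent,synthetic_demo,WT,1
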