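key,value
onset.breast.20_29.first,0.0002
onset.breast.20_29.last,0.0020
onset.breast.30_39.first,0.0106
onset.breast.30_39.last,0.0185
onset.breast.40_49.first,0.0326
onset.breast.40_49.last,0.0688
onset.breast.50_59.first,0.0705
onset.breast.50_59.last,0.0723
onset.breast.60_69.first,0.0740
onset.breast.60_69.last,0.0757
onset.breast.70_79.first,0.0666
onset.breast.70_79.last,0.0638
onset.breast.80_89.first,0.0609
onset.breast.80_89.last,0.0583
onset.breast.90_99.first,0.0557
onset.breast.90_99.last,0.0531
onset.ovarian.20_29.first,0.000015
onset.ovarian.20_29.last,0.00002
onset.ovarian.30_39.first,0.0019
onset.ovarian.30_39.last,0.0025
onset.ovarian.40_49.first,0.0119
onset.ovarian.40_49.last,0.0178
onset.ovarian.50_59.first,0.0242
onset.ovarian.50_59.last,0.0242
onset.ovarian.60_69.first,0.0348
onset.ovarian.60_69.last,0.0433
onset.ovarian.70_79.first,0.0465
onset.ovarian.70_79.last,0.0553
onset.ovarian.80_89.first,0.0497
onset.ovarian.80_89.last,0.0441
onset.ovarian.90_99.first,0.0385
onset.ovarian.90_99.last,0.0328
prog.breast.s1_s2,0.205
prog.breast.s2_s3,0.25
prog.breast.s3_s4,0.60
prog.ovarian.s1_s2,0.70
prog.ovarian.s2_s3,0.93
prog.ovarian.s3_s4,0.99
det.breast.s1,0.23
det.breast.s2,0.55
det.breast.s3,0.60
det.breast.s4,1.00
det.ovarian.s1,0.15
det.ovarian.s2,0.15
det.ovarian.s3,0.72
det.ovarian.s4,0.95
surv5.breast.s1,0.993
surv5.breast.s2,0.876
surv5.breast.s3,0.595
surv5.breast.s4,0.262
surv5.ovarian.s1,0.871
surv5.ovarian.s2,0.704
surv5.ovarian.s3,0.350
surv5.ovarian.s4,0.155
effect.rr_breast_pbm,0.070
effect.rr_breast_pbso,0.500
effect.rr_breast_both,0.039
effect.rr_ovarian_pbso,0.038
util.well,0.92
util.remission,0.83
util.detected.breast.s1,0.68
util.detected.breast.s2,0.61
util.detected.breast.s3,0.56
util.detected.breast.s4,0.42
util.detected.ovarian.s1,0.81
util.detected.ovarian.s2,0.72
util.detected.ovarian.s3,0.63
util.detected.ovarian.s4,0.55
util.surgery.pbm,0.88
util.surgery.pbso,0.95
util.surgery.both,0.84
cost.surveillance,608
cost.surveillance_after_pbm_fraction,0.5
cost.surgery.pbm,9032
cost.surgery.pbso,3099
cost.surgery.both,12131
cost.initial.breast.early.none,20092
cost.initial.breast.early.pbm,14333
cost.initial.breast.early.pbso,20092
cost.initial.breast.early.both,14333
cost.initial.breast.metastatic.none,30623
cost.initial.breast.metastatic.pbm,24865
cost.initial.breast.metastatic.pbso,30623
cost.initial.breast.metastatic.both,24865
cost.initial.ovarian.nonadvanced.none,13666
cost.initial.ovarian.nonadvanced.pbm,13666
cost.initial.ovarian.nonadvanced.pbso,11280
cost.initial.ovarian.nonadvanced.both,11280
cost.initial.ovarian.advanced.none,35052
cost.initial.ovarian.advanced.pbm,35052
cost.initial.ovarian.advanced.pbso,32666
cost.initial.ovarian.advanced.both,32666
cost.followup.breast.s1.none,595
cost.followup.breast.s1.pbm,443
cost.followup.breast.s1.pbso,595
cost.followup.breast.s1.both,443
cost.followup.breast.s2.none,652
cost.followup.breast.s2.pbm,500
cost.followup.breast.s2.pbso,652
cost.followup.breast.s2.both,500
cost.followup.breast.s3.none,589
cost.followup.breast.s3.pbm,437
cost.followup.breast.s3.pbso,589
cost.followup.breast.s3.both,437
cost.followup.breast.s4.none,686
cost.followup.breast.s4.pbm,534
cost.followup.breast.s4.pbso,686
cost.followup.breast.s4.both,534
cost.followup.ovarian.nonadvanced.none,1356
cost.followup.ovarian.nonadvanced.pbm,1052
cost.followup.ovarian.nonadvanced.pbso,1214
cost.followup.ovarian.nonadvanced.both,910
cost.followup.ovarian.advanced.none,2389
cost.followup.ovarian.advanced.pbm,2085
cost.followup.ovarian.advanced.pbso,2246
cost.followup.ovarian.advanced.both,1942
cost.followup_years.breast,10
cost.followup_years.ovarian,5
cost.palliative.breast,12103
cost.palliative.ovarian,12103
analysis.discount_rate,0.03
analysis.wtp,90000
analysis.start_age,30
analysis.end_age,100
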