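date,location,new_cases_smoothed_per_million
2020-01-01,Atlantis,0.514
2020-01-02,Atlantis,0.939
2020-01-03,Atlantis,1.374
2020-01-04,Atlantis,2.292
2020-01-05,Atlantis,3.764
2020-01-06,Atlantis,5.133
2020-01-07,Atlantis,7.508
2020-01-08,Atlantis,10.555
2020-01-09,Atlantis,14.732
2020-01-10,Atlantis,20.059
2020-01-11,Atlantis,27.279
2020-01-12,Atlantis,31.851
2020-01-13,Atlantis,38.794
2020-01-14,Atlantis,48.218
2020-01-15,Atlantis,54.16
2020-01-16,Atlantis,63.704
2020-01-17,Atlantis,68.933
2020-01-18,Atlantis,69.346
2020-01-19,Atlantis,79.66
2020-01-20,Atlantis,79.174
2020-01-21,Atlantis,81.79
2020-01-22,Atlantis,78.582
2020-01-23,Atlantis,74.869
2020-01-24,Atlantis,65.896
2020-01-25,Atlantis,58.415
2020-01-26,Atlantis,47.956
2020-01-27,Atlantis,42.872
2020-01-28,Atlantis,34.921
2020-01-29,Atlantis,25.298
2020-01-30,Atlantis,19.279
2020-01-31,Atlantis,15.091
2020-02-01,Atlantis,11.318
2020-02-02,Atlantis,8.36
2020-02-03,Atlantis,5.521
2020-02-04,Atlantis,3.729
2020-02-05,Atlantis,2.374
2020-02-06,Atlantis,1.388
2020-02-07,Atlantis,0.82
2020-02-08,Atlantis,0.495
2020-02-09,Atlantis,0.308
2020-01-01,Lemuria,0.476
2020-01-02,Lemuria,0.694
2020-01-03,Lemuria,1.098
2020-01-04,Lemuria,1.667
2020-01-05,Lemuria,2.247
2020-01-06,Lemuria,3.239
2020-01-07,Lemuria,4.237
2020-01-08,Lemuria,6.336
2020-01-09,Lemuria,8.357
2020-01-10,Lemuria,10.681
2020-01-11,Lemuria,15.689
2020-01-12,Lemuria,18.074
2020-01-13,Lemuria,24.778
2020-01-14,Lemuria,29.834
2020-01-15,Lemuria,36.501
2020-01-16,Lemuria,45.551
2020-01-17,Lemuria,58.244
2020-01-18,Lemuria,61.351
2020-01-19,Lemuria,73.498
2020-01-20,Lemuria,92.753
2020-01-21,Lemuria,97.473
2020-01-22,Lemuria,99.903
2020-01-23,Lemuria,124.826
2020-01-24,Lemuria,117.815
2020-01-25,Lemuria,131.492
2020-01-26,Lemuria,129.49
2020-01-27,Lemuria,138.699
2020-01-28,Lemuria,153.824
2020-01-29,Lemuria,146.873
2020-01-30,Lemuria,132.685
2020-01-31,Lemuria,127.036
2020-02-01,Lemuria,126.007
2020-02-02,Lemuria,109.854
2020-02-03,Lemuria,101.296
2020-02-04,Lemuria,99.918
2020-02-05,Lemuria,84.372
2020-02-06,Lemuria,76.252
2020-02-07,Lemuria,68.379
2020-02-08,Lemuria,53.979
2020-02-09,Lemuria,42.62
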