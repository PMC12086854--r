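# Polarized split-valence contracted Gaussian basis (6-31G**-like), NWChem text format.
H S
     18.73113700         0.03349460
      2.82539370         0.23472695
      0.64012170         0.81375733
H S
      0.16127780         1.00000000
O S
   5484.67170000         0.00183110
    825.23495000         0.01395010
    188.04696000         0.06844510
     52.96450000         0.23271430
     16.89757000         0.47019300
      5.79963530         0.35852090
O SP
     15.53961600        -0.11077750        0.07087430
      3.59993360        -0.14802630        0.33975280
      1.01376180         1.13076700        0.72715860
O SP
      0.27000580         1.00000000        1.00000000
F S
   7001.71309000         0.00181962
   1051.36609000         0.01391608
    239.28569000         0.06840532
     67.39744530         0.23318576
     19.51999810         0.47126744
      6.60044358         0.35661855
F SP
     20.84795280        -0.10850697        0.07162872
      4.80830834        -0.14645166        0.34591210
      1.34406986         1.12868858        0.72246996
F SP
      0.35815139         1.00000000        1.00000000
H P
      1.10000000         1.00000000
O D
      0.80000000         1.00000000
F D
      0.80000000         1.00000000
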