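# Minimal contracted Gaussian basis (STO-3G-like), NWChem text format.
# Elements: H, O, F.
H S
      3.42525091         0.15432897
      0.62391373         0.53532814
      0.16885540         0.44463454
O S
    130.70932000         0.15432897
     23.80886100         0.53532814
      6.44360830         0.44463454
O SP
      5.03315130        -0.09996723        0.15591627
      1.16959610         0.39951283        0.60768372
      0.38038900         0.70011547        0.39195739
F S
    166.67913000         0.15432897
     30.36081200         0.53532814
      8.21682070         0.44463454
F SP
      6.46480320        -0.09996723        0.15591627
      1.50228120         0.39951283        0.60768372
      0.48858850         0.70011547        0.39195739
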