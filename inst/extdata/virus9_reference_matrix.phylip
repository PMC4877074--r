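    9
AlMV-3     0.0000 1.5387 4.4078 5.2166 2.6300 4.7192 3.9887 1.7040 4.4352
APMV-3     1.5387 0.0000 5.4632 7.0070 2.9442 6.2642 5.0473 1.5851 5.6373
AVII       4.4078 5.4632 0.0000 2.0993 2.6788 1.0170 0.9822 4.1554 2.1266
CiLRV-3    5.2166 7.0070 2.0993 0.0000 4.6843 1.6580 1.9534 6.0340 1.2103
CVV-3      2.6300 2.9442 2.6788 4.6843 0.0000 3.4462 2.8271 1.9629 4.1915
EMV-3      4.7192 6.2642 1.0170 1.6580 3.4462 0.0000 1.0041 4.7944 2.0004
LRMV-3     3.9887 5.0473 0.9822 1.9534 2.8271 1.0041 0.0000 3.7523 1.7026
PDV-3      1.7040 1.5851 4.1554 6.0340 1.9629 4.7944 3.7523 0.0000 4.8894
TSV-3      4.4352 5.6373 2.1266 1.2103 4.1915 2.0004 1.7026 4.8894 0.0000
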