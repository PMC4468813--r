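NADP_generated_conformer
     RDKit          3D

 76 80  0  0  0  0  0  0  0  0999 V2000
   11.3077   -1.5664   -0.4314 N   0  0  0  0  0  0  0  0  0  0  0  0
   10.4288   -0.6664    0.1012 C   0  0  0  0  0  0  0  0  0  0  0  0
   10.7941    0.2045    0.8956 O   0  0  0  0  0  0  0  0  0  0  0  0
    9.0007   -0.7120   -0.2801 C   0  0  0  0  0  0  0  0  0  0  0  0
    8.4564   -1.5203   -1.2686 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.0984   -1.4089   -1.5591 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.3077   -0.5065   -0.8483 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.8537    0.2820    0.1133 N   0  0  0  0  0  4  0  0  0  0  0  0
    8.1717    0.1791    0.4016 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.0208    1.1975    0.9279 C   0  0  2  0  0  0  0  0  0  0  0  0
    4.8112    0.5544    1.3323 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.7012    1.4524    1.0621 C   0  0  2  0  0  0  0  0  0  0  0  0
    2.9551    0.9987   -0.1870 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8361   -0.4032   -0.1961 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.3047   -1.0583   -1.5812 P   0  0  0  0  0  0  0  0  0  0  0  0
    3.1366   -0.4608   -2.6859 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.1875   -2.5471   -1.3911 O   0  0  0  0  0  1  0  0  0  0  0  0
    0.8155   -0.4496   -1.5821 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2004   -1.1216   -0.5503 P   0  0  0  0  0  0  0  0  0  0  0  0
    0.0785   -0.9709    0.9182 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3266   -2.6430   -1.0710 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6159   -0.4910   -1.0095 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7657   -1.0494   -0.4101 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3496   -0.0558    0.6057 C   0  0  1  0  0  0  0  0  0  0  0  0
   -3.9897    1.0350   -0.0997 O   0  0  0  0  0  0  0  0  0  0  0  0
   -5.4048    1.0298    0.1967 C   0  0  1  0  0  0  0  0  0  0  0  0
   -6.0869    0.4718   -0.9522 N   0  0  0  0  0  0  0  0  0  0  0  0
   -5.7743    0.8068   -2.2542 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.5521    0.1925   -3.1219 N   0  0  0  0  0  0  0  0  0  0  0  0
   -7.4458   -0.5164   -2.3515 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.5383   -1.3305   -2.6927 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.9153   -1.5644   -4.0007 N   0  0  0  0  0  0  0  0  0  0  0  0
   -9.2643   -1.8822   -1.6984 N   0  0  0  0  0  0  0  0  0  0  0  0
   -8.8881   -1.6509   -0.4285 C   0  0  0  0  0  0  0  0  0  0  0  0
   -7.8687   -0.8892    0.0112 N   0  0  0  0  0  0  0  0  0  0  0  0
   -7.1857   -0.3435   -1.0058 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.5055    0.3317    1.5475 C   0  0  2  0  0  0  0  0  0  0  0  0
   -5.1662    1.2899    2.5620 O   0  0  0  0  0  0  0  0  0  0  0  0
   -6.3839    1.9588    3.3583 P   0  0  0  0  0  0  0  0  0  0  0  0
   -6.1023    3.1607    4.1862 O   0  0  0  0  0  0  0  0  0  0  0  0
   -7.5768    2.0894    2.3022 O   0  0  0  0  0  0  0  0  0  0  0  0
   -6.9194    0.7397    4.2422 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4317   -0.7326    1.4484 C   0  0  2  0  0  0  0  0  0  0  0  0
   -3.9857   -1.1595    2.7301 O   0  0  0  0  0  0  0  0  0  0  0  0
    4.3304    2.8254    0.8618 C   0  0  1  0  0  0  0  0  0  0  0  0
    4.6393    3.4424    2.1235 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.6538    2.4818    0.1879 C   0  0  1  0  0  0  0  0  0  0  0  0
    6.6220    3.5172    0.3441 O   0  0  0  0  0  0  0  0  0  0  0  0
   11.1476   -2.0998   -1.2693 H   0  0  0  0  0  0  0  0  0  0  0  0
   12.2836   -1.3840   -0.1879 H   0  0  0  0  0  0  0  0  0  0  0  0
    9.0627   -2.2413   -1.8170 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.6357   -2.0170   -2.3356 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.2488   -0.4130   -1.0679 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.5538    0.8312    1.1921 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.5848    1.4239    1.8388 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0413    1.4138    1.9399 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.5021    1.3219   -1.0752 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.9597    1.4558   -0.2183 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6127   -2.9849   -1.1899 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4812   -1.2459   -1.2155 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5293   -2.0089    0.0694 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5477    0.3798    1.2175 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.7335    2.0741    0.2596 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.9638    1.4988   -2.4974 H   0  0  0  0  0  0  0  0  0  0  0  0
   -9.8012   -2.0075   -4.1887 H   0  0  0  0  0  0  0  0  0  0  0  0
   -8.3578   -1.1336   -4.7378 H   0  0  0  0  0  0  0  0  0  0  0  0
   -9.4811   -2.1522    0.3345 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.4738   -0.1203    1.7869 H   0  0  0  0  0  0  0  0  0  0  0  0
   -8.3639    1.6453    2.6670 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.3557    0.6612    5.0405 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.8381   -1.6144    0.9296 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3580   -1.8897    2.6087 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7201    3.5294    0.2937 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7872    3.6792    2.5597 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.5215    2.2981   -0.8843 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.3549    4.0143    1.1444 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  2  4  1  0
  4  5  2  0
  5  6  1  0
  6  7  2  0
  7  8  1  0
  8  9  2  0
  8 10  1  0
 10 11  1  0
 11 12  1  0
 12 13  1  0
 13 14  1  0
 14 15  1  0
 15 16  2  0
 15 17  1  0
 15 18  1  0
 18 19  1  0
 19 20  2  0
 19 21  1  0
 19 22  1  0
 22 23  1  0
 23 24  1  0
 24 25  1  0
 25 26  1  0
 26 27  1  0
 27 28  1  0
 28 29  2  0
 29 30  1  0
 30 31  2  0
 31 32  1  0
 31 33  1  0
 33 34  2  0
 34 35  1  0
 35 36  2  0
 26 37  1  0
 37 38  1  0
 38 39  1  0
 39 40  2  0
 39 41  1  0
 39 42  1  0
 37 43  1  0
 43 44  1  0
 12 45  1  0
 45 46  1  0
 45 47  1  0
 47 48  1  0
  9  4  1  0
 47 10  1  0
 43 24  1  0
 36 27  1  0
 36 30  1  0
  1 49  1  0
  1 50  1  0
  5 51  1  0
  6 52  1  0
  7 53  1  0
  9 54  1  0
 10 55  1  1
 12 56  1  1
 13 57  1  0
 13 58  1  0
 21 59  1  0
 23 60  1  0
 23 61  1  0
 24 62  1  1
 26 63  1  1
 28 64  1  0
 32 65  1  0
 32 66  1  0
 34 67  1  0
 37 68  1  1
 41 69  1  0
 42 70  1  0
 43 71  1  6
 44 72  1  0
 45 73  1  6
 46 74  1  0
 47 75  1  6
 48 76  1  0
M  CHG  2   8   1  17  -1
M  END
$$$$
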