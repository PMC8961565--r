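H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
R PMID:7108955
A Kyte, J. and Doolittle, R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
C GRAR740102    0.886  JANJ780102    0.843
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500
    3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200
//
H SYNTH000001
D Synthetic linearly increasing scale (test fixture, not a measured property)
R
A none (synthetic)
T Synthetic fixture entry
J none
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.000   2.000   3.000   4.000   5.000   6.000   7.000   8.000   9.000  10.000
   11.000  12.000  13.000  14.000  15.000  16.000  17.000  18.000  19.000  20.000
//
H SYNTH000002
D Synthetic scale with a missing tryptophan value (test fixture)
R
A none (synthetic)
T Synthetic fixture entry with NA
J none
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.100   0.200   0.300   0.400   0.500   0.600   0.700   0.800   0.900   1.000
    1.100   1.200   1.300   1.400   1.500   1.600   1.700      NA   1.900   2.000
//
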