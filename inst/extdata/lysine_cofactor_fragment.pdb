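ATOM      1  N   LYS P   4      -2.402   1.452  -3.102  1.00  0.00           N
ATOM      2  CA  LYS P   4      -1.850   0.702  -1.980  1.00  0.00           C
ATOM      3  C   LYS P   4      -2.630   0.905  -0.690  1.00  0.00           C
ATOM      4  O   LYS P   4      -3.710   1.490  -0.700  1.00  0.00           O
ATOM      5  CB  LYS P   4      -0.390   1.090  -1.760  1.00  0.00           C
ATOM      6  CG  LYS P   4       0.480   0.820  -2.980  1.00  0.00           C
ATOM      7  CD  LYS P   4       1.241   0.000  -0.879  1.00  0.00           C
ATOM      8  CE  LYS P   4       0.900  -0.350  -0.450  1.00  0.00           C
ATOM      9  NZ  LYS P   4       0.000   0.000   0.000  1.00  0.00           N
HETATM   10  N   SAM X 900       2.900   1.800   6.500  1.00  0.00           N
HETATM   11  CE  SAM X 900       0.000   0.000   3.500  1.00  0.00           C
HETATM   12  SD  SAM X 900       0.420   0.110   5.290  1.00  0.00           S
HETATM   13  CG  SAM X 900       1.950   0.900   5.700  1.00  0.00           C
END
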