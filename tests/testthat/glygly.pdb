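ATOM      1 N    GLY A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2 CA   GLY A   1       1.460   0.000   0.000  1.00  0.00           C
ATOM      3 C    GLY A   1       2.005   1.419   0.000  1.00  0.00           C
ATOM      4 O    GLY A   1       0.940   2.034   0.000  1.00  0.00           O
ATOM      5 N    GLY A   2       3.315   1.188   0.000  1.00  0.00           N
ATOM      6 CA   GLY A   2       4.152   2.384   0.000  1.00  0.00           C
ATOM      7 C    GLY A   2       5.649   2.120   0.000  1.00  0.00           C
ATOM      8 O    GLY A   2       6.070   3.276   0.000  1.00  0.00           O
ATOM      9 OXT  GLY A   2       5.866   0.889   0.000  1.00  0.00           O
HETATM   10 O    HOH A   3       2.000  -4.000   1.000  1.00  0.00           O
HETATM   11 H1   HOH A   3       2.760  -4.000   1.580  1.00  0.00           H
HETATM   12 H2   HOH A   3       1.240  -4.000   1.580  1.00  0.00           H
END
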