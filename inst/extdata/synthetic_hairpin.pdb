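REMARK synthetic two-strand mini-hairpin fixture (not a real protein)
REMARK 30 atoms; designed inter-strand N-H...O=C hydrogen bonds
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  H   ALA A   1       0.450   0.893   0.000  1.00  0.00           H
ATOM      3  CA  ALA A   1       1.450  -0.550   0.000  1.00  0.00           C
ATOM      4  C   ALA A   1       2.500   0.400   0.000  1.00  0.00           C
ATOM      5  O   ALA A   1       2.600   1.650   0.000  1.00  0.00           O
ATOM      6  N   ALA A   2       3.800   0.000   0.000  1.00  0.00           N
ATOM      7  H   ALA A   2       4.250   0.893   0.000  1.00  0.00           H
ATOM      8  CA  ALA A   2       5.250  -0.550   0.000  1.00  0.00           C
ATOM      9  C   ALA A   2       6.300   0.400   0.000  1.00  0.00           C
ATOM     10  O   ALA A   2       6.400   1.650   0.000  1.00  0.00           O
ATOM     11  N   ALA A   3       7.600   0.000   0.000  1.00  0.00           N
ATOM     12  H   ALA A   3       8.050   0.893   0.000  1.00  0.00           H
ATOM     13  CA  ALA A   3       9.050  -0.550   0.000  1.00  0.00           C
ATOM     14  C   ALA A   3      10.100   0.400   0.000  1.00  0.00           C
ATOM     15  O   ALA A   3      10.200   1.650   0.000  1.00  0.00           O
ATOM     16  N   GLY B   4      -2.550   4.550   0.000  1.00  0.00           N
ATOM     17  H   GLY B   4      -2.550   5.550   0.000  1.00  0.00           H
ATOM     18  CA  GLY B   4      -1.100   5.050   0.000  1.00  0.00           C
ATOM     19  C   GLY B   4       0.000   4.100   0.000  1.00  0.00           C
ATOM     20  O   GLY B   4       0.000   2.900   0.000  1.00  0.00           O
ATOM     21  N   GLY B   5       1.250   4.550   0.000  1.00  0.00           N
ATOM     22  H   GLY B   5       1.250   5.550   0.000  1.00  0.00           H
ATOM     23  CA  GLY B   5       2.700   5.050   0.000  1.00  0.00           C
ATOM     24  C   GLY B   5       3.800   4.100   0.000  1.00  0.00           C
ATOM     25  O   GLY B   5       3.800   2.900   0.000  1.00  0.00           O
ATOM     26  N   GLY B   6       5.050   4.550   0.000  1.00  0.00           N
ATOM     27  H   GLY B   6       5.050   5.550   0.000  1.00  0.00           H
ATOM     28  CA  GLY B   6       6.500   5.050   0.000  1.00  0.00           C
ATOM     29  C   GLY B   6       7.600   4.100   0.000  1.00  0.00           C
ATOM     30  O   GLY B   6       7.600   2.900   0.000  1.00  0.00           O
END
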