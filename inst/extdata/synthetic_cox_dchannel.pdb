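REMARK   SYNTHETIC stand-in: D-channel neighbourhood geometry only,
REMARK   not an experimental structure.
ATOM      1  N   ASN A  80       0.000   0.000   0.000  1.00 30.00           N
ATOM      2  CA  ASN A  80       1.000   0.400   0.300  1.00 30.00           C
ATOM      3  C   ASN A  80       1.800  -0.500   0.000  1.00 30.00           C
ATOM      4  O   ASN A  80       2.200  -1.300   0.500  1.00 30.00           O
ATOM      5  CB  ASN A  80       0.800   1.300  -0.400  1.00 30.00           C
ATOM      6  CG  ASN A  80       1.200   2.200   0.200  1.00 30.00           C
ATOM      7  OD1 ASN A  80       0.600   3.000   0.800  1.00 30.00           O
ATOM      8  ND2 ASN A  80       2.000   2.900  -0.300  1.00 30.00           N
ATOM      9  N   VAL A  83       4.800   0.500   0.000  1.00 30.00           N
ATOM     10  CA  VAL A  83       5.800   0.900   0.300  1.00 30.00           C
ATOM     11  C   VAL A  83       6.600   0.000   0.000  1.00 30.00           C
ATOM     12  O   VAL A  83       7.000  -0.800   0.500  1.00 30.00           O
ATOM     13  CB  VAL A  83       5.600   1.800  -0.400  1.00 30.00           C
ATOM     14  CG1 VAL A  83       6.000   2.700   0.200  1.00 30.00           C
ATOM     15  CG2 VAL A  83       5.400   3.500   0.800  1.00 30.00           C
ATOM     16  N   ASP A  91       5.000   7.600   1.000  1.00 30.00           N
ATOM     17  CA  ASP A  91       6.000   8.000   1.300  1.00 30.00           C
ATOM     18  C   ASP A  91       6.800   7.100   1.000  1.00 30.00           C
ATOM     19  O   ASP A  91       7.200   6.300   1.500  1.00 30.00           O
ATOM     20  CB  ASP A  91       5.800   8.900   0.600  1.00 30.00           C
ATOM     21  CG  ASP A  91       6.200   9.800   1.200  1.00 30.00           C
ATOM     22  OD1 ASP A  91       5.600  10.600   1.800  1.00 30.00           O
ATOM     23  OD2 ASP A  91       7.000  10.500   0.700  1.00 30.00           O
ATOM     24  N   ALA A 153      20.000   0.000   0.000  1.00 30.00           N
ATOM     25  CA  ALA A 153      21.000   0.400   0.300  1.00 30.00           C
ATOM     26  C   ALA A 153      21.800  -0.500   0.000  1.00 30.00           C
ATOM     27  O   ALA A 153      22.200  -1.300   0.500  1.00 30.00           O
ATOM     28  CB  ALA A 153      20.800   1.300  -0.400  1.00 30.00           C
ATOM     29  N   PHE A 238      24.500   8.200   1.000  1.00 30.00           N
ATOM     30  CA  PHE A 238      25.500   8.600   1.300  1.00 30.00           C
ATOM     31  C   PHE A 238      26.300   7.700   1.000  1.00 30.00           C
ATOM     32  O   PHE A 238      26.700   6.900   1.500  1.00 30.00           O
ATOM     33  CB  PHE A 238      25.300   9.500   0.600  1.00 30.00           C
ATOM     34  CG  PHE A 238      25.700  10.400   1.200  1.00 30.00           C
ATOM     35  CD1 PHE A 238      25.100  11.200   1.800  1.00 30.00           C
ATOM     36  CD2 PHE A 238      26.500  11.100   0.700  1.00 30.00           C
ATOM     37  CE1 PHE A 238      26.000  10.100   2.100  1.00 30.00           C
ATOM     38  CE2 PHE A 238      26.900  10.600   2.400  1.00 30.00           C
ATOM     39  CZ  PHE A 238      26.400  11.500   1.900  1.00 30.00           C
ATOM     40  N   GLU A 242      20.500   8.800   0.000  1.00 30.00           N
ATOM     41  CA  GLU A 242      21.500   9.200   0.300  1.00 30.00           C
ATOM     42  C   GLU A 242      22.300   8.300   0.000  1.00 30.00           C
ATOM     43  O   GLU A 242      22.700   7.500   0.500  1.00 30.00           O
ATOM     44  CB  GLU A 242      21.300  10.100  -0.400  1.00 30.00           C
ATOM     45  CG  GLU A 242      21.700  11.000   0.200  1.00 30.00           C
ATOM     46  CD  GLU A 242      21.100  11.800   0.800  1.00 30.00           C
ATOM     47  OE1 GLU A 242      22.500  11.700  -0.300  1.00 30.00           O
ATOM     48  OE2 GLU A 242      22.000  10.700   1.100  1.00 30.00           O
END
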