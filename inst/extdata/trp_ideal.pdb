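REMARK   Idealized free tryptophan (force-field optimized geometry)
ATOM      1  N   TRP A   1      -2.715   0.117  -1.365  1.00  0.00           N
ATOM      2  CA  TRP A   1      -2.157   0.018   0.014  1.00  0.00           C
ATOM      3  C   TRP A   1      -3.275   0.161   1.056  1.00  0.00           C
ATOM      4  O   TRP A   1      -3.147   0.433   2.239  1.00  0.00           O
ATOM      5  CB  TRP A   1      -1.074   1.080   0.276  1.00  0.00           C
ATOM      6  CG  TRP A   1       0.229   0.781  -0.402  1.00  0.00           C
ATOM      7  CD1 TRP A   1       0.636   1.237  -1.640  1.00  0.00           C
ATOM      8  CD2 TRP A   1       1.294  -0.029   0.112  1.00  0.00           C
ATOM      9  NE1 TRP A   1       1.881   0.731  -1.898  1.00  0.00           N
ATOM     10  CE2 TRP A   1       2.309  -0.042  -0.845  1.00  0.00           C
ATOM     11  CE3 TRP A   1       1.486  -0.757   1.305  1.00  0.00           C
ATOM     12  CZ2 TRP A   1       3.507  -0.745  -0.670  1.00  0.00           C
ATOM     13  CZ3 TRP A   1       2.678  -1.465   1.496  1.00  0.00           C
ATOM     14  CH2 TRP A   1       3.672  -1.458   0.521  1.00  0.00           C
ATOM     15  OXT TRP A   1      -4.509  -0.095   0.560  1.00  0.00           O
END
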