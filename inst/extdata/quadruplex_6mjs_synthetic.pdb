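REMARK 999 SYNTHETIC STAND-IN, NOT DEPOSITED COORDINATES.
REMARK 999 FOUR TRP INDOLE SIDE CHAINS REPRODUCING THE PUBLISHED
REMARK 999 SHORTEST C/N DISTANCES OF THE 6MJS A/D QUADRUPLEX
REMARK 999 (DIAGONALS 3.7 AND 5.4 ANGSTROM); BUILT BY gen_quadruplex().
ATOM      1  CG  TRP A 124      -1.306   1.851   0.000  1.00  0.00           C
ATOM      2  CD1 TRP A 124      -1.325   0.451   0.000  1.00  0.00           C
ATOM      3  CD2 TRP A 124       0.031   2.265   0.000  1.00  0.00           C
ATOM      4  NE1 TRP A 124       0.000   0.000   0.000  1.00  0.00           N
ATOM      5  CE2 TRP A 124       0.838   1.121   0.000  1.00  0.00           C
ATOM      6  CE3 TRP A 124       0.618   3.536   0.000  1.00  0.00           C
ATOM      7  CZ2 TRP A 124       2.232   1.249   0.000  1.00  0.00           C
ATOM      8  CZ3 TRP A 124       2.012   3.663   0.000  1.00  0.00           C
ATOM      9  CH2 TRP A 124       2.819   2.520   0.000  1.00  0.00           C
ATOM     10  CG  TRP A 122       5.175  -1.224   0.662  1.00  0.00           C
ATOM     11  CD1 TRP A 122       6.279  -0.685  -0.008  1.00  0.00           C
ATOM     12  CD2 TRP A 122       4.494  -2.062  -0.229  1.00  0.00           C
ATOM     13  NE1 TRP A 122       6.281  -1.190  -1.314  1.00  0.00           N
ATOM     14  CE2 TRP A 122       5.178  -2.041  -1.450  1.00  0.00           C
ATOM     15  CE3 TRP A 122       3.340  -2.841  -0.086  1.00  0.00           C
ATOM     16  CZ2 TRP A 122       4.708  -2.800  -2.529  1.00  0.00           C
ATOM     17  CZ3 TRP A 122       2.870  -3.600  -1.164  1.00  0.00           C
ATOM     18  CH2 TRP A 122       3.553  -3.579  -2.386  1.00  0.00           C
ATOM     19  CG  TRP D 122       2.364  -0.759   3.527  1.00  0.00           C
ATOM     20  CD1 TRP D 122       0.985  -0.537   3.631  1.00  0.00           C
ATOM     21  CD2 TRP D 122       3.011   0.475   3.657  1.00  0.00           C
ATOM     22  NE1 TRP D 122       0.781   0.834   3.825  1.00  0.00           N
ATOM     23  CE2 TRP D 122       2.033   1.460   3.841  1.00  0.00           C
ATOM     24  CE3 TRP D 122       4.365   0.830   3.631  1.00  0.00           C
ATOM     25  CZ2 TRP D 122       2.409   2.799   4.000  1.00  0.00           C
ATOM     26  CZ3 TRP D 122       4.741   2.169   3.790  1.00  0.00           C
ATOM     27  CH2 TRP D 122       3.763   3.154   3.974  1.00  0.00           C
ATOM     28  CG  TRP D 124       9.071   5.071  -1.022  1.00  0.00           C
ATOM     29  CD1 TRP D 124       8.152   5.964  -0.460  1.00  0.00           C
ATOM     30  CD2 TRP D 124       9.059   3.898  -0.258  1.00  0.00           C
ATOM     31  NE1 TRP D 124       7.572   5.344   0.653  1.00  0.00           N
ATOM     32  CE2 TRP D 124       8.132   4.067   0.778  1.00  0.00           C
ATOM     33  CE3 TRP D 124       9.772   2.699  -0.370  1.00  0.00           C
ATOM     34  CZ2 TRP D 124       7.918   3.036   1.701  1.00  0.00           C
ATOM     35  CZ3 TRP D 124       9.558   1.668   0.553  1.00  0.00           C
ATOM     36  CH2 TRP D 124       8.631   1.836   1.588  1.00  0.00           C
TER
END
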