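H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H KLEP840101
D Net charge (Klein et al., 1984)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.      1.      0.     -1.      0.      0.     -1.      0.      0.      0.
     0.      1.      0.      0.      0.      0.      0.      0.      0.      0.
//
H FAUJ880111
D Positive charge (Fauchere et al., 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.      1.      0.      0.      0.      0.      0.      0.      1.      0.
     0.      1.      0.      0.      0.      0.      0.      0.      0.      0.
//
H FAUJ880112
D Negative charge (Fauchere et al., 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.      0.      0.      1.      0.      0.      1.      0.      0.      0.
     0.      0.      0.      0.      0.      0.      0.      0.      0.      0.
//
H pI
D Isoelectric point of the free amino acid
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    6.00   10.76    5.41    2.77    5.05    5.65    3.22    5.97    7.59    6.02
    5.98    9.74    5.74    5.48    6.30    5.68    5.66    5.89    5.66    5.96
//
H MW
D Molecular weight of the free amino acid (Da)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   89.09  174.20  132.12  133.10  121.16  146.15  147.13   75.07  155.16  131.17
  131.17  146.19  149.21  165.19  115.13  105.09  119.12  204.23  181.19  117.15
//
H MV
D Molecular volume of the residue (A^3, Zamyatnin-style)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    88.6   173.4   114.1   111.1   108.5   143.8   138.4    60.1   153.2   166.7
   166.7   168.6   162.9   189.9   112.7    89.0   116.1   227.8   193.6   140.0
//
H MEIH800101
D SYNTHETIC STAND-IN: average reduced distance for C-alpha (burial-like
D scale). The reference database values were unavailable offline; these
D are documented approximations, not the published scale.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.77    1.01    0.93    0.92    0.68    0.96    0.94    0.87    0.88    0.64
    0.66    1.05    0.67    0.64    0.93    0.86    0.83    0.71    0.79    0.65
//
H VASM830102
D SYNTHETIC STAND-IN: relative population of conformational state E
D (extended-state propensity-like scale). Documented approximation; the
D published values were unavailable offline.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.06    0.07    0.06    0.05    0.09    0.07    0.05    0.05    0.08    0.12
    0.09    0.07    0.09    0.11    0.02    0.08    0.10    0.10    0.11    0.13
//
H CHAM830107
D SYNTHETIC STAND-IN: parameter of charge transfer capability (indicator-
D like scale). Documented approximation; the published values were
D unavailable offline.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.      1.      1.      1.      0.      1.      1.      0.      1.      0.
     0.      1.      0.      0.      0.      0.      0.      1.      1.      0.
//
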