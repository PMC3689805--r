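strain,mean_induced_lethality,marker_5prime,marker_3prime
QX57,0.00098,CB4856,CB4856
QX56,0.00279,CB4856,CB4856
QX145,0.00380,CB4856,CB4856
QX236,0.00403,CB4856,CB4856
QX113,0.00420,CB4856,CB4856
QX169,0.00549,CB4856,CB4856
QX127,0.01111,CB4856,CB4856
QX115,0.02231,CB4856,CB4856
QX1,0.02427,CB4856,CB4856
QX218,0.0324,CB4856,CB4856
QX158,0.07819,CB4856,CB4856
QX7,0.11031,CB4856,CB4856
QX168,0.11475,CB4856,CB4856
QX217,0.15780,N2,N2
QX24,0.34959,N2,N2
QX64,0.55530,N2,N2
QX13,0.97357,N2,N2
QX222,0.97357,CB4856,CB4856
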