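# International 10-20 layout, 19 scalp channels + A1/A2 earlobes
# label x y z (meters; x right, y anterior, z superior)
Fp1	-0.029389	0.090451	0.030902
Fp2	0.029389	0.090451	0.030902
F7	-0.076942	0.055902	0.030902
F3	-0.034500	0.067400	0.065300
Fz	0.000000	0.058779	0.080902
F4	0.034500	0.067400	0.065300
F8	0.076942	0.055902	0.030902
T7	-0.095106	0.000000	0.030902
C3	-0.058779	0.000000	0.080902
Cz	0.000000	0.000000	0.100000
C4	0.058779	0.000000	0.080902
T8	0.095106	0.000000	0.030902
P7	-0.076942	-0.055902	0.030902
P3	-0.034500	-0.067400	0.065300
Pz	0.000000	-0.058779	0.080902
P4	0.034500	-0.067400	0.065300
P8	0.076942	-0.055902	0.030902
O1	-0.029389	-0.090451	0.030902
O2	0.029389	-0.090451	0.030902
A1	-0.080000	-0.030000	-0.045000
A2	0.080000	-0.030000	-0.045000
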