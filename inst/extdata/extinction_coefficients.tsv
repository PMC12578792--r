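wavelength_nm	eps_hbo	eps_hbr
690	276.0	2051.96
710	334.0	1497.00
730	390.0	1102.20
750	518.0	1405.24
760	586.0	1548.52
770	650.0	1311.88
780	710.0	1075.44
800	816.0	761.72
810	864.0	717.08
820	916.0	693.76
830	974.0	693.04
840	1022.0	692.36
850	1058.0	691.32
870	1128.0	726.00
900	1198.0	761.84
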