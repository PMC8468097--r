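3.12.6.1 | Pathway_02
3.12.6.1 | Pathway_06
2.20.6.3 | Pathway_01
3.11.20.6 | Pathway_03
3.11.20.6 | Pathway_05
4.13.18.10 | Pathway_06
3.9.1.11 | Pathway_05
3.9.1.11 | Pathway_06
1.17.20.14 | Pathway_06
4.5.11.17 | Pathway_02
2.18.13.18 | Pathway_01
2.18.13.18 | Pathway_06
4.14.17.19 | Pathway_01
4.14.17.19 | Pathway_05
3.17.10.20 | Pathway_03
3.17.10.20 | Pathway_05
4.8.8.21 | Pathway_06
2.5.7.23 | Pathway_02
2.5.7.23 | Pathway_05
3.11.9.24 | Pathway_01
1.10.20.25 | Pathway_03
1.10.20.25 | Pathway_04
1.4.11.26 | Pathway_02
1.4.11.26 | Pathway_03
2.4.10.28 | Pathway_04
3.16.9.29 | Pathway_01
3.16.9.29 | Pathway_06
6.15.11.30 | Pathway_01
6.15.11.30 | Pathway_04
6.15.4.32 | Pathway_01
6.15.4.32 | Pathway_05
3.5.17.34 | Pathway_01
3.5.17.34 | Pathway_05
4.6.6.35 | Pathway_01
4.6.6.35 | Pathway_04
1.7.9.38 | Pathway_06
5.7.3.39 | Pathway_01
6.1.20.40 | Pathway_01
6.1.20.40 | Pathway_02
5.12.20.41 | Pathway_01
5.12.20.41 | Pathway_02
5.12.19.43 | Pathway_03
5.12.19.43 | Pathway_04
4.9.8.44 | Pathway_05
6.14.16.46 | Pathway_02
6.14.16.46 | Pathway_05
3.7.13.47 | Pathway_04
3.7.13.47 | Pathway_05
6.13.18.48 | Pathway_02
6.10.9.49 | Pathway_04
6.10.9.49 | Pathway_06
2.12.14.50 | Pathway_05
1.20.20.51 | Pathway_01
4.12.15.52 | Pathway_02
4.12.15.52 | Pathway_06
5.2.10.53 | Pathway_04
5.2.10.53 | Pathway_06
5.18.9.55 | Pathway_02
5.11.15.56 | Pathway_04
1.3.13.57 | Pathway_03
1.3.13.57 | Pathway_04
5.17.9.58 | Pathway_05
5.17.9.58 | Pathway_06
3.17.20.60 | Pathway_05
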