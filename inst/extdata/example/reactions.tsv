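R00001 | 3.12.6.1 | C00001 | C00007 | forward
R00002 | 1.8.6.2 | C00002 | C00008 | forward
R00003 | 2.20.6.3 | C00003 | C00009 | forward
R00004 | 6.17.8.4 | C00004 | C00010 | forward
R00005 | 4.17.3.5 | C00005 | C00011 | forward
R00006 | 3.11.20.6 | C00006 | C00012 | forward
R00007 | 1.8.3.7 | C00004;C00007 | C00013 | forward
R00008 | 3.13.3.8 | C00011 | C00014 | forward
R00009 | 1.2.16.9 | C00014 | C00015 | forward
R00010 | 4.13.18.10 | C00015;C00009 | C00016 | forward
R00011 | 3.9.1.11 | C00007 | C00017 | forward
R00012 | 4.7.15.12 | C00003 | C00018 | forward
R00013 | 4.15.5.13 | C00008 | C00019 | forward
R00014 | 1.17.20.14 | C00004;C00017 | C00020 | forward
R00015 | 4.8.1.15 | C00002;C00005 | C00021 | forward
R00016 | 2.19.18.16 | C00021 | C00022 | forward
R00017 | 4.5.11.17 | C00005;C00007 | C00023 | forward
R00018 | 2.18.13.18 | C00018;C00019 | C00024 | forward
R00019 | 4.14.17.19 | C00006;C00007 | C00025 | forward
R00020 | 3.17.10.20 | C00015;C00023 | C00026 | forward
R00021 | 4.8.8.21 | C00018 | C00027 | forward
R00022 | 5.19.9.22 | C00015 | C00028 | forward
R00023 | 2.5.7.23 | C00024 | C00029 | forward
R00024 | 3.11.9.24 | C00006 | C00030 | forward
R00025 | 1.10.20.25 | C00020;C00008 | C00031 | forward
R00026 | 1.4.11.26 | C00019;C00002 | C00032 | forward
R00027 | 4.2.12.27 | C00017;C00027 | C00033 | forward
R00028 | 2.4.10.28 | C00031;C00017 | C00034 | forward
R00029 | 3.16.9.29 | C00009 | C00035 | forward
R00030 | 6.15.11.30 | C00027 | C00036 | forward
R00031 | 2.6.6.31 | C00011 | C00037 | forward
R00032 | 6.15.4.32 | C00036 | C00038 | forward
R00033 | 4.19.2.33 | C00015;C00009 | C00039 | forward
R00034 | 3.5.17.34 | C00019 | C00040 | forward
R00035 | 4.6.6.35 | C00040 | C00019 | forward
R00036 | 1.1.19.36 | C00028 | C00014 | forward
R00037 | 6.4.18.37 | C00033 | C00007 | forward
R00038 | 1.7.9.38 | C00019 | C00008 | forward
R00039 | 5.7.3.39 | C00027 | C00018 | forward
R00040 | 6.1.20.40 | C00031 | C00020 | forward
R00041 | 5.12.20.41 | C00017 | C00007 | forward
R00042 | 6.12.8.42 | C00029 | C00024 | forward
R00043 | 5.12.19.43 | C00035 | C00009 | forward
R00044 | 4.9.8.44 | C00015 | C00014 | forward
R00045 | 4.18.1.45 | C00015 | C00011 | forward
R00046 | 6.14.16.46 | C00026 | C00011 | forward
R00047 | 3.7.13.47 | C00038 | C00018 | forward
R00048 | 6.13.18.48 | C00033 | C00017 | forward
R00049 | 6.10.9.49 | C00036 | C00027 | forward
R00050 | 2.12.14.50 | C00016 | C00011 | forward
R00051 | 1.20.20.51 | C00014 | C00011 | forward
R00052 | 4.12.15.52 | C00029 | C00018 | forward
R00053 | 5.2.10.53 | C00037 | C00011 | forward
R00054 | 2.11.4.54 | C00028 | C00011 | forward
R00055 | 5.18.9.55 | C00035 | C00040 | reversible
R00056 | 5.11.15.56 | C00032 | C00009 | reversible
R00057 | 1.3.13.57 | C00012 | C00010 | reversible
R00058 | 5.17.9.58 | C00025 | C00012 | reversible
R00059 | 2.16.6.59 | C00026 | C00030 | reversible
R00060 | 3.17.20.60 | C00030 | C00028 | reversible
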