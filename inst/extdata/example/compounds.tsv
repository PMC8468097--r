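C00001 | compound C00001
C00002 | compound C00002
C00003 | compound C00003
C00004 | compound C00004
C00005 | compound C00005
C00006 | compound C00006
C00007 | compound C00007
C00008 | compound C00008
C00009 | compound C00009
C00010 | compound C00010
C00011 | compound C00011
C00012 | compound C00012
C00013 | compound C00013
C00014 | compound C00014
C00015 | compound C00015
C00016 | compound C00016
C00017 | compound C00017
C00018 | compound C00018
C00019 | compound C00019
C00020 | compound C00020
C00021 | compound C00021
C00022 | compound C00022
C00023 | compound C00023
C00024 | compound C00024
C00025 | compound C00025
C00026 | compound C00026
C00027 | compound C00027
C00028 | compound C00028
C00029 | compound C00029
C00030 | compound C00030
C00031 | compound C00031
C00032 | compound C00032
C00033 | compound C00033
C00034 | compound C00034
C00035 | compound C00035
C00036 | compound C00036
C00037 | compound C00037
C00038 | compound C00038
C00039 | compound C00039
C00040 | compound C00040
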