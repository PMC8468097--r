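C00001 | Pathway_02
C00002 | Pathway_02
C00003 | Pathway_06
C00005 | Pathway_05
C00006 | Pathway_02
C00007 | Pathway_01
C00007 | Pathway_04
C00008 | Pathway_01
C00008 | Pathway_02
C00009 | Pathway_03
C00009 | Pathway_04
C00012 | Pathway_01
C00012 | Pathway_04
C00013 | Pathway_01
C00014 | Pathway_04
C00014 | Pathway_06
C00015 | Pathway_04
C00015 | Pathway_06
C00016 | Pathway_05
C00016 | Pathway_06
C00017 | Pathway_01
C00020 | Pathway_05
C00022 | Pathway_04
C00023 | Pathway_06
C00024 | Pathway_04
C00024 | Pathway_05
C00026 | Pathway_04
C00027 | Pathway_04
C00028 | Pathway_01
C00029 | Pathway_02
C00029 | Pathway_06
C00031 | Pathway_03
C00032 | Pathway_03
C00032 | Pathway_05
C00033 | Pathway_01
C00034 | Pathway_03
C00034 | Pathway_04
C00035 | Pathway_03
C00035 | Pathway_05
C00036 | Pathway_03
C00037 | Pathway_05
C00038 | Pathway_01
C00038 | Pathway_05
C00039 | Pathway_04
C00039 | Pathway_06
C00040 | Pathway_05
C00040 | Pathway_06
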