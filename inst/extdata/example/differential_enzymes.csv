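ec,logFC,PValue,FDR,association
1.1.19.36,-3.81061837242382,0.00563220674161519,0.00844831011242278,soil
1.10.20.25,2.70633543446702,0.00180246913297153,0.00270370369945729,root
1.17.20.14,2.94654168099044,0.00830311229175061,0.0124546684376259,root
1.2.16.9,-0.426425123600473,0.435151013010181,0.652726519515272,not_associated
1.20.20.51,-3.73518449564208,0.00616916036776905,0.00925374055165357,soil
1.3.13.57,3.01498499353814,0.00367063591127259,0.00550595386690889,root
1.4.11.26,-2.87799815018479,0.00861774911562174,0.0129266236734326,soil
1.7.9.38,-0.436405464738092,0.163335268874653,0.245002903311979,not_associated
1.8.3.7,2.35322630640389,0.00233496921162342,0.00350245381743513,root
1.8.6.2,2.13214167253464,0.000478057802298858,0.000717086703448287,root
2.11.4.54,0.0349166124310543,0.401601322635543,0.602401983953314,not_associated
2.12.14.50,2.4912996967818,0.000447731250134043,0.000671596875201064,root
2.16.6.59,-3.0775843555668,0.00844406661640147,0.0126660999246022,soil
2.18.13.18,-2.73966353065155,0.00974657604900391,0.0146198640735059,soil
2.19.18.16,3.4503399805076,0.000530784151054234,0.000796176226581351,root
2.20.6.3,-0.237646215418131,0.535318834136706,0.802978251205059,not_associated
2.4.10.28,-2.85711837597822,0.00996170434506581,0.0149425565175987,soil
2.5.7.23,2.51327853306818,0.00963287979289211,0.0144493196893382,root
2.6.6.31,2.19577316505865,0.00980461724548679,0.0147069258682302,root
3.11.20.6,-3.04694098579491,0.00206989446412259,0.00310484169618389,soil
3.11.9.24,-0.150087239191768,0.0534662176272832,0.0801993264409248,not_associated
3.12.6.1,2.87346831532073,0.00793545197629722,0.0119031779644458,root
3.13.3.8,0.01312239811764,0.212629221437965,0.318943832156947,not_associated
3.16.9.29,-0.110645426019834,0.404522809432819,0.606784214149229,not_associated
3.17.10.20,-3.70071503815057,0.0093259547918581,0.0139889321877871,soil
3.17.20.60,2.42918667248639,0.00468258304012818,0.00702387456019227,root
3.5.17.34,3.59159771495239,0.000456844875025598,0.000685267312538397,root
3.7.13.47,3.48697670175466,0.00312262460545915,0.00468393690818872,root
3.9.1.11,2.873200106691,0.00677671115005716,0.0101650667250857,root
4.12.15.52,2.25919986571775,0.00801702886512612,0.0120255432976892,root
4.13.18.10,0.00481306049855754,0.654210130847059,0.981315196270589,not_associated
4.14.17.19,3.20129198094615,0.003296091848308,0.004944137772462,root
4.15.5.13,2.91690444975283,0.00168768925618811,0.00253153388428217,root
4.17.3.5,4.67273912357611,0.00337955328510854,0.00506932992766282,root
4.18.1.45,-3.47078962045376,0.00823474602813731,0.012352119042206,soil
4.19.2.33,-0.295084023053665,0.702681901364122,1,not_associated
4.2.12.27,4.41411485120909,0.0088429132382513,0.0132643698573769,root
4.5.11.17,0.485025567826528,0.21305462383898,0.31958193575847,not_associated
4.6.6.35,3.08429857641497,0.0064838574551354,0.0097257861827031,root
4.7.15.12,-2.80230354008703,0.00399438812023318,0.00599158218034977,soil
4.8.1.15,-0.104469527279182,0.149668403540272,0.224502605310408,not_associated
4.8.8.21,3.75374364193911,0.00932491126691153,0.0139873669003673,root
4.9.8.44,-2.68805690550026,0.00651898379690612,0.00977847569535918,soil
5.11.15.56,2.73256029863391,0.00319998684010081,0.00479998026015121,root
5.12.19.43,-0.311816136172063,0.222002236999106,0.333003355498658,not_associated
5.12.20.41,3.13856253016294,0.00481064978710183,0.00721597468065275,root
5.17.9.58,5.36579840962528,0.00603014789763885,0.00904522184645827,root
5.18.9.55,-0.417762776926189,0.997328213369474,1,not_associated
5.19.9.22,0.294601575146476,0.304977132892236,0.457465699338354,not_associated
5.2.10.53,3.48475659971759,0.00965802901628326,0.0144870435244249,root
5.7.3.39,-4.09323764306589,0.00160451200985871,0.00240676801478807,soil
6.1.20.40,-3.30290840511423,0.00167813400555822,0.00251720100833733,soil
6.10.9.49,-0.650065583068804,0.181559247465339,0.272338871198008,not_associated
6.12.8.42,-4.01529943636837,0.00143805451768278,0.00215708177652418,soil
6.13.18.48,-0.0434742445564868,0.377419487037696,0.566129230556544,not_associated
6.14.16.46,-0.372008130767449,0.488008770067245,0.732013155100867,not_associated
6.15.11.30,-5.45359292676654,0.00940194765539324,0.0141029214830899,soil
6.15.4.32,-0.476479438967592,0.654077657591552,0.981116486387327,not_associated
6.17.8.4,2.75437917563298,0.00608067456944645,0.00912101185416967,root
6.4.18.37,3.54151933941865,0.00788442958759023,0.0118266443813854,root
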