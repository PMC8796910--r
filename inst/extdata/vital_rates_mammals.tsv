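species	order	LS	lits_per_year	b	delta	S_alpha	Z	M	r
Ochotona princeps	Lagomorpha	2.73	2.00	2.73	0.357	0.210	0.157	0.047	2.1723
Ochotona curzoniae	Lagomorpha	4.57	2.00	2.10	0.285	0.156	0.418	0.324	0.1125
Lepus europaeus	Lagomorpha	2.46	3.99	4.91	0.155	0.423	0.108	0.058	4.2540
Oryctolagus cuniculus	Lagomorpha	4.74	5.09	12.10	0.135	●	●	0.283	●
Sylvilagus floridanus	Lagomorpha	3.86	4.58	8.84	0.098	0.425	0.202	0.128	6.4550
Myocaster coypus	Rodentia	4.54	2.76	6.26	0.208	0.273	0.154	0.079	5.0340
Spermophilus armatus	Rodentia	4.99	0.89	2.22	0.280	0.288	0.104	0.055	1.9043
Spermophilus beldingi	Rodentia	5.00	0.82	2.05	0.300	0.284	0.105	0.054	1.7525
Spermophilus dauricus	Rodentia	●	0.82	●	●	0.328	0.093	0.052	●
Spermophilus lateralis	Rodentia	5.15	0.82	2.11	0.421	0.156	0.108	0.050	1.8023
Marmota flaviventris	Rodentia	4.15	0.82	1.70	●	0.161	0.051	0.033	1.5752
Tamias striatus	Rodentia	4.14	1.75	3.62	0.300	0.359	0.140	0.110	2.9071
Sciurus carolinensis	Rodentia	2.85	1.67	2.38	0.229	0.316	0.115	0.049	1.5562
Tamiasciurus hudsonicus	Rodentia	3.82	0.82	1.57	0.299	0.291	0.091	0.057	1.3522
Zapus hudsonius	Rodentia	5.40	0.82	2.21	0.422	0.110	0.184	●	●
Zapus princeps	Rodentia	4.46	0.70	1.56	●	0.301	0.076	0.052	1.3770
Apodemus flavicollis	Rodentia	5.96	2.88	8.59	0.325	0.415	0.301	0.303	4.4560
Clethrionomys glareolus	Rodentia	4.86	3.39	8.24	0.450	0.390	0.494	0.274	-0.1804
Peromyscus leucopus	Rodentia	4.89	●	●	0.471	●	●	0.440	●
Peromyscus maniculatus	Rodentia	4.28	4.67	9.99	0.389	0.407	0.391	0.316	3.1140
Macaca sinica	Primates	1.00	0.69	0.34	●	0.168	0.031	0.005	0.3240
Pan troglodytes	Primates	1.05	0.19	0.10	0.247	0.384	0.007	0.006	0.0933
Talpa europaea	Insectivora	4.10	0.82	1.68	●	0.494	0.059	0.061	1.5097
Tachyoryctes splendens	Insectivora	1.50	2.11	1.59	●	0.523	0.124	0.045	1.3181
Erinaceus europaeus	Insectivora	4.47	1.73	3.87	0.180	●	●	0.033	●
Ailuropoda melanoleuca	Carnivora	1.56	0.70	0.55	0.083	0.394	0.024	0.020	0.5161
Ursus americanus	Carnivora	2.30	0.42	0.49	0.271	●	●	0.015	●
Phoca hispida	Carnivora	1.00	0.80	0.40	0.149	0.234	0.029	0.008	0.3801
Halichoerus grypus	Carnivora	1.00	0.85	0.43	0.255	0.290	0.021	0.012	0.4086
Mirounga leonina	Carnivora	1.00	0.86	0.43	0.212	0.376	0.016	0.021	0.4015
Callorhinus ursinus	Carnivora	1.00	0.78	0.39	0.304	0.260	0.024	0.010	0.3703
Lutra canadensis	Carnivora	2.52	0.82	1.03	0.328	0.166	0.046	0.022	0.9578
Mustela putorius	Carnivora	5.88	0.82	2.41	●	0.261	0.112	0.029	2.0761
Mephitis mephitis	Carnivora	6.16	0.82	2.53	0.383	0.361	0.085	0.061	2.2300
Taxidea taxus	Carnivora	2.80	0.47	0.66	0.732	0.308	0.060	0.053	0.5619
Canis lupus	Carnivora	6.80	0.82	2.79	0.194	0.219	0.127	0.046	2.3360
Urocyon cinereoargenteus	Carnivora	4.42	0.95	2.10	0.146	●	●	0.029	●
Vulpes vulpes	Carnivora	4.85	0.82	1.99	0.559	●	●	0.046	●
Alopex lagopus	Carnivora	11.3	0.83	4.68	●	0.429	0.079	0.055	4.2204
Felis catus	Carnivora	4.40	1.60	3.52	0.401	0.193	0.137	0.069	2.8871
Lynx rufus	Carnivora	2.64	0.82	1.09	0.168	0.213	0.102	0.052	0.9113
Sus scrofa	Artiodactyla	5.28	0.82	2.16	0.364	0.184	0.075	0.046	1.9368
Phacochoerus aethiopicus	Artiodactyla	2.79	0.72	1.00	●	0.153	0.074	0.028	0.8913
Hippopotamus amphibius	Artiodactyla	1.00	0.33	0.17	0.165	0.411	0.013	0.005	0.1628
Aepyceros melampus	Artiodactyla	1.00	0.90	0.45	0.357	0.753	0.012	0.020	0.4241
Kobus ellipsiprymnus	Artiodactyla	1.00	1.11	0.56	●	0.488	0.033	0.015	0.5257
Kobus kob	Artiodactyla	1.00	1.30	0.65	0.534	●	●	0.032	●
Damaliscus lunatus	Artiodactyla	1.00	0.57	0.28	●	●	●	0.056	●
Syncerus caffer	Artiodactyla	1.00	0.40	0.20	0.303	●	●	0.016	●
Rupicapra rupicapra	Artiodactyla	1.00	0.88	0.44	●	0.754	0.010	0.029	0.4057
Hemitragus jemlahicus	Artiodactyla	1.04	●	●	●	0.442	0.026	0.019	●
Ovis dalli	Artiodactyla	1.00	0.75	0.38	●	0.587	0.016	0.015	0.3586
Moschus berezovskii	Artiodactyla	1.41	●	●	●	0.488	0.020	0.014	●
Cervus elaphus	Artiodactyla	1.00	0.82	0.41	0.341	0.602	0.015	0.019	0.3844
Capreolus capreolus	Artiodactyla	2.17	●	●	●	0.389	0.039	0.028	●
Alces alces	Artiodactyla	1.17	0.81	0.47	0.231	0.403	0.031	0.023	0.4314
Rangifer tarandus	Artiodactyla	1.20	0.82	0.49	0.361	0.663	0.010	0.013	0.4721
Odocoileus hemionus	Artiodactyla	1.58	0.94	0.74	0.286	●	●	0.025	●
Equus caballus	Perissodactyla	1.00	0.49	0.25	●	0.394	0.019	0.010	0.2351
Equus burchelli	Perissodactyla	1.00	0.58	0.29	0.535	0.673	0.011	0.010	0.2770
Loxodonta africana	Proboscidea	1.06	0.14	0.08	0.217	0.465	0.004	0.005	0.0750
Rhinolophus ferrumequinum	Chiroptera	1.00	0.82	0.41	●	●	●	0.020	●
Eptesicus fuscus	Chiroptera	1.64	0.82	0.68	0.529	●	●	0.024	●
Pipistrellus subflavus	Chiroptera	2.00	0.82	0.82	●	●	●	0.046	●
Pipistrellus pipistrellus	Chiroptera	1.26	0.82	0.51	0.621	●	●	0.038	●
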