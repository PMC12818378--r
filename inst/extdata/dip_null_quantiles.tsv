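n	p0.001	p0.002	p0.005	p0.01	p0.02	p0.05	p0.1	p0.2	p0.3	p0.4	p0.5	p0.6	p0.7	p0.8	p0.9	p0.95	p0.98	p0.99	p0.995	p0.998	p0.999
4	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.1250000119	0.125000012
5	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.0999999785	0.1101345572	0.1361902604	0.1547402909	0.1702720988	0.1787391482	0.1847726361	0.1893302304	0.191511952
6	0.0833333516	0.0833333516	0.0833333516	0.0833333516	0.0833333516	0.0833333516	0.0833333516	0.0833333516	0.0833333516	0.0833333516	0.0919161081	0.1019699340	0.1130303779	0.1252897725	0.1398561063	0.1491982105	0.1579054028	0.1614431468	0.1639529810	0.1653626578	0.166191033
7	0.0714285827	0.0714285827	0.0714285827	0.0714285827	0.0714285827	0.0714285827	0.0714285827	0.0740090909	0.0830281558	0.0912154298	0.0986744404	0.1061895509	0.1140025611	0.1219398093	0.1307763543	0.1370545149	0.1416460040	0.1473090190	0.1589385086	0.1674975730	0.173610175
8	0.0625000215	0.0625000215	0.0625000215	0.0625000215	0.0625000215	0.0625000215	0.0675415235	0.0774604554	0.0853072929	0.0916576829	0.0974524546	0.1028862157	0.1084621978	0.1143966985	0.1212389512	0.1250971577	0.1395089316	0.1481464733	0.1554778510	0.1645614134	0.169278735
10	0.0499999738	0.0499999738	0.0501328955	0.0533884450	0.0570425645	0.0627539990	0.0687820997	0.0762248073	0.0815329790	0.0856858401	0.0894336104	0.0929519229	0.0962553821	0.0996120524	0.1107673950	0.1200434563	0.1295164078	0.1353386634	0.1401414871	0.1470565925	0.150961201
12	0.0459312600	0.0476734974	0.0503514827	0.0525407974	0.0560178383	0.0609177814	0.0660729523	0.0715696321	0.0752356143	0.0781997838	0.0807972646	0.0831004100	0.0886893477	0.0955979161	0.1046974301	0.1116427486	0.1192437787	0.1249787745	0.1316527381	0.1426816755	0.145407935
15	0.0440597165	0.0454490597	0.0481281600	0.0502802364	0.0529491668	0.0567208245	0.0601139722	0.0637412858	0.0661566000	0.0699371190	0.0740888643	0.0779503160	0.0822149491	0.0876766114	0.0946800289	0.1015134327	0.1110292619	0.1166862367	0.1208282830	0.1268324449	0.132431832
20	0.0400496404	0.0413184161	0.0430951616	0.0447437480	0.0463507979	0.0489209621	0.0516205602	0.0562379222	0.0598271189	0.0629782033	0.0657567906	0.0688806434	0.0724494953	0.0773635297	0.0844226379	0.0907279403	0.0982692715	0.1030883228	0.1075477333	0.1131315186	0.116734831
25	0.0367306262	0.0373722245	0.0386422860	0.0398206503	0.0416959661	0.0447697282	0.0476845794	0.0514567857	0.0543381009	0.0570361524	0.0597330570	0.0628304219	0.0661557631	0.0705016141	0.0769550915	0.0824548583	0.0897491547	0.0938878470	0.0980578880	0.1035894723	0.107611171
30	0.0334644542	0.0343046297	0.0357824933	0.0372477834	0.0390104997	0.0414331360	0.0439109907	0.0472146544	0.0498837819	0.0525423217	0.0551141143	0.0577538342	0.0607303829	0.0650208220	0.0712540841	0.0769222622	0.0831058910	0.0885481310	0.0932393164	0.0976410556	0.103090471
40	0.0293669150	0.0301232050	0.0316763392	0.0327048309	0.0339728211	0.0362479718	0.0386241679	0.0416288037	0.0439997339	0.0462451615	0.0486870503	0.0511195045	0.0539227881	0.0575250211	0.0631023793	0.0679614947	0.0742801284	0.0785035024	0.0827985420	0.0883470494	0.093018196
50	0.0261606363	0.0271520707	0.0284576033	0.0294693748	0.0310284211	0.0330623131	0.0350871038	0.0378076510	0.0400721402	0.0421559567	0.0441940689	0.0463766646	0.0489465666	0.0518755326	0.0567173004	0.0613295112	0.0669397594	0.0704542447	0.0741341125	0.0783410074	0.081344855
75	0.0221808031	0.0228664533	0.0237421548	0.0244994128	0.0256019127	0.0275652738	0.0292310872	0.0315170989	0.0333066916	0.0350721335	0.0368085337	0.0387482448	0.0409642525	0.0436615539	0.0479111981	0.0520313509	0.0567458178	0.0599743758	0.0628955734	0.0684451372	0.070941271
100	0.0193909754	0.0200554331	0.0211789318	0.0218530855	0.0227162322	0.0242478423	0.0256841545	0.0277537694	0.0292751241	0.0307867465	0.0322924614	0.0340167241	0.0359307594	0.0384407182	0.0421393499	0.0458344421	0.0500596231	0.0528497076	0.0553947111	0.0585623843	0.059721664
150	0.0161523525	0.0165993899	0.0172112031	0.0179492459	0.0187155723	0.0199413884	0.0211921277	0.0229147973	0.0243462062	0.0255964341	0.0268811464	0.0282653880	0.0299918575	0.0320829577	0.0352039900	0.0380706294	0.0417311002	0.0444605694	0.0464966623	0.0481874750	0.049682317
200	0.0138744965	0.0141557620	0.0150669512	0.0155769935	0.0162451835	0.0173930182	0.0185607700	0.0200455699	0.0213015690	0.0224256434	0.0236480570	0.0249415841	0.0264001875	0.0282111726	0.0310758562	0.0334982464	0.0369909891	0.0394552423	0.0413199264	0.0444127583	0.046236497
300	0.0116464227	0.0119630511	0.0125563329	0.0130347869	0.0135745336	0.0145324290	0.0154577827	0.0166822171	0.0177779193	0.0188067231	0.0197818756	0.0208471599	0.0220620170	0.0235848966	0.0260038247	0.0282778633	0.0309552272	0.0326291599	0.0345657750	0.0366285418	0.038646407
500	0.0087059420	0.0091463497	0.0096264993	0.0101119546	0.0106560151	0.0114756079	0.0120981803	0.0131314597	0.0139299192	0.0146875281	0.0154454470	0.0163151069	0.0172905879	0.0184046264	0.0201139498	0.0219939625	0.0241375865	0.0253728714	0.0263252117	0.0279094481	0.028567923
750	0.0075080381	0.0077664700	0.0081585766	0.0084593033	0.0087908233	0.0093452563	0.0100096030	0.0109060111	0.0115754781	0.0122166038	0.0128268528	0.0134511981	0.0142201633	0.0151961093	0.0169027052	0.0184695752	0.0200803122	0.0212411553	0.0222177279	0.0232266601	0.024279065
1000	0.0065592035	0.0066989566	0.0069887931	0.0073195419	0.0076001232	0.0081414301	0.0087485766	0.0094434590	0.0100497966	0.0105526004	0.0111442590	0.0117357688	0.0124306636	0.0133839030	0.0148536830	0.0160628991	0.0175570147	0.0184617063	0.0197919711	0.0206574212	0.021882286
1500	0.0055003536	0.0055675345	0.0058336182	0.0060958049	0.0062533142	0.0066925311	0.0071663055	0.0077748189	0.0082549906	0.0086921420	0.0092040706	0.0097030187	0.0102987561	0.0110524287	0.0122607770	0.0133278744	0.0145040499	0.0153021802	0.0158220232	0.0166085723	0.017138492
2000	0.0046804985	0.0049754854	0.0051089973	0.0052935015	0.0055255257	0.0059362581	0.0063386245	0.0068428912	0.0072646446	0.0076628919	0.0080383086	0.0084774871	0.0089612169	0.0096138787	0.0106892672	0.0115735316	0.0125979169	0.0133553070	0.0142722138	0.0152093178	0.015937607
3000	0.0039114981	0.0040868119	0.0041592618	0.0043172958	0.0045514505	0.0048554487	0.0051739225	0.0056188226	0.0059323559	0.0062410169	0.0065640283	0.0069224849	0.0073568034	0.0078709388	0.0087005353	0.0093835592	0.0103181797	0.0110184210	0.0116052191	0.0124187025	0.012632820
5000	0.0030886191	0.0031485821	0.0032737098	0.0033652366	0.0035155949	0.0037849884	0.0040426946	0.0043975062	0.0046851964	0.0049516492	0.0052047682	0.0054744878	0.0058266215	0.0062446618	0.0068911929	0.0074370573	0.0081651254	0.0087988793	0.0094342822	0.0098936242	0.010486321
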