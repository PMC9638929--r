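# synthetic known-good peak-volume collection
# generated by polyprof::make_known_good_collection(fixture_spec(seed = 20220818), 31, perturb_sd = 0.05)
# columns: peak label, then one synthetic dataset per column
peak	synthetic_01	synthetic_02	synthetic_03	synthetic_04	synthetic_05	synthetic_06	synthetic_07	synthetic_08	synthetic_09	synthetic_10	synthetic_11	synthetic_12	synthetic_13	synthetic_14	synthetic_15	synthetic_16	synthetic_17	synthetic_18	synthetic_19	synthetic_20	synthetic_21	synthetic_22	synthetic_23	synthetic_24	synthetic_25	synthetic_26	synthetic_27	synthetic_28	synthetic_29	synthetic_30	synthetic_31
40S	0.1037848371	0.09756810607	0.09643686083	0.09054013642	0.1002594645	0.1070231433	0.1007777897	0.09343298403	0.09432023317	0.09022482279	0.08883293519	0.09679680306	0.1023243662	0.09760481059	0.09430672927	0.09840650529	0.1053463819	0.1013369469	0.099122588	0.1007929987	0.09873506181	0.1081777218	0.1026373062	0.1007661698	0.098136611	0.09136590841	0.1051761455	0.09270751269	0.0979755321	0.09557365185	0.1016079143
60S	0.1779677322	0.1839947048	0.1764246546	0.1834126718	0.1841921196	0.1934528619	0.1598558236	0.184233014	0.1900039976	0.1953946646	0.1685099672	0.168591936	0.1775657121	0.1959971891	0.1642509693	0.1721446469	0.1765548269	0.1968013731	0.1801606304	0.1985451548	0.1896640787	0.2020601863	0.1854251631	0.1882996986	0.1906017384	0.1782624794	0.184992121	0.1790325258	0.1847416182	0.1810330077	0.1897648782
1	0.6670569115	0.667123047	0.6761335399	0.6773443107	0.6625225049	0.6444917714	0.689667673	0.6706532954	0.6620336763	0.6608104571	0.6915608274	0.6866208199	0.6668272673	0.6523019103	0.6912924219	0.6790583636	0.6629790955	0.6491693319	0.6713803633	0.648584408	0.6561202425	0.6363564758	0.6618131339	0.6609399592	0.656801465	0.6795031305	0.6525929605	0.678221204	0.6633570186	0.6696280201	0.6567548048
2	0.01681427511	0.01679156441	0.01689267993	0.01588320987	0.01854927208	0.0177637104	0.01564307693	0.01716699947	0.01716768071	0.01899477005	0.01753650688	0.01538706338	0.01819391569	0.01767521741	0.01655820817	0.01618215211	0.01840313326	0.01716377613	0.0167022693	0.01709932063	0.01876692723	0.01816038845	0.01622183469	0.01599426729	0.01804478361	0.0164447375	0.01881997775	0.0172837553	0.01772408135	0.01698757935	0.01697605708
3	0.01226253884	0.01211571006	0.01201499683	0.01190008883	0.01213724261	0.01297247069	0.01189420475	0.01164085289	0.01251573409	0.01234894875	0.01142973471	0.01141078534	0.01225666694	0.01192925582	0.01141966485	0.01102736177	0.01247615074	0.0122239485	0.01143356164	0.0115958141	0.01269330382	0.01212438743	0.01196904078	0.01157371999	0.01254682818	0.01224064631	0.01347354059	0.01119137251	0.01313881825	0.01302935002	0.0124918552
4	0.009282189119	0.009142692576	0.009089516255	0.008500432235	0.009100373735	0.009800231383	0.009202819347	0.009765286359	0.01020965764	0.009013870143	0.009353594602	0.008985412398	0.009650492161	0.0102348658	0.008933571446	0.0102446126	0.01055217169	0.01004332611	0.008771116913	0.009707127204	0.01027973582	0.009613475512	0.009270490746	0.008853686732	0.009704948645	0.009511210978	0.01018111439	0.008867073313	0.00952028791	0.01000581798	0.009437769385
5	0.004905442365	0.005059063967	0.005126648952	0.004839959245	0.005328584937	0.005672478574	0.005003899524	0.004968137528	0.005067731492	0.005078105435	0.005120441583	0.004609861596	0.004971454732	0.005535387057	0.004982878996	0.004841435691	0.005162845733	0.004954931657	0.004832438021	0.005134491348	0.005232764083	0.005291275818	0.005029950919	0.005270683801	0.005316045921	0.004836720069	0.005694206755	0.004663386545	0.005398292031	0.005441998943	0.004895407032
6	0.002595496789	0.002849870919	0.002717117582	0.002698996638	0.002560039757	0.00306080698	0.002567892431	0.002552469928	0.002817842447	0.002836588162	0.00252758204	0.002577630335	0.002777061773	0.003111377272	0.002836387067	0.002634683298	0.002770384739	0.002697392072	0.0024654215	0.00290406733	0.002728691693	0.002573485303	0.002595617764	0.002732283264	0.003035271631	0.002739632294	0.002973349433	0.002584181519	0.002758167056	0.00271508612	0.002690265062
7	0.001328853325	0.001301802023	0.001238933272	0.001195357249	0.001248651954	0.001451164824	0.001269470312	0.001413766381	0.001389953456	0.001185265233	0.001223389417	0.001257493462	0.001305599729	0.001343142147	0.001322313406	0.001242775236	0.001457411798	0.001440954385	0.001309836778	0.001386862809	0.001468522687	0.001267644652	0.001240204924	0.001372829435	0.001330595011	0.001238330353	0.001582951716	0.001303419818	0.001343675113	0.001353565346	0.001199462132
8	0.0008868592554	0.0008133767159	0.0008696770408	0.0007786408198	0.0008883671119	0.0008752034847	0.0008671886505	0.0008092820146	0.0009950900156	0.0008634178223	0.0007912864547	0.0008026587525	0.0008729084092	0.0008993283508	0.0008533805303	0.000896647031	0.0009454285265	0.000912300025	0.0008428656881	0.0009692977241	0.0009054220265	0.0009615195965	0.0008819096302	0.0008164795393	0.00097580913	0.0008955326575	0.0009232832406	0.0009051137788	0.0008493353194	0.0008958121186	0.0009394547712
9	0.0002953443321	0.0003096050073	0.0003157366307	0.0002878781434	0.0003188705536	0.000355544977	0.0002996560954	0.0003333964478	0.0003145585461	0.0003425320159	0.0003296678561	0.000284220019	0.0003386392339	0.0003121380015	0.0003105085584	0.0003190912188	0.0003543150061	0.0003380502858	0.0002922173739	0.0003520998362	0.0003213924828	0.0003552450501	0.000310311923	0.0003202729078	0.0003287401954	0.000323646645	0.0003293667222	0.0003009248345	0.0003043626554	0.0002876682671	0.0003306015106
10	0.0006761170604	0.00071310777	0.000677564507	0.0006192329498	0.0007279486307	0.0007651372904	0.0005989557053	0.0007392685658	0.000749779864	0.0006316737064	0.0006534454545	0.0006271786202	0.0007212424932	0.0006818239614	0.000672329153	0.0006835097132	0.0007418190626	0.0006512502131	0.0006885262476	0.0007209008174	0.0006937107368	0.0007291164155	0.0006702844362	0.0007083375412	0.0006821083272	0.0006382962879	0.000820147324	0.0007031543211	0.0006695053372	0.0006772394882	0.000720927953
11	0.00118911792	0.001234723569	0.001218189483	0.001153053712	0.001252375904	0.001263208165	0.001321172656	0.001261609671	0.001334426872	0.001324307506	0.001226022078	0.001106860242	0.001259075159	0.001343461968	0.001284971613	0.001278402249	0.001287135429	0.001220732388	0.001110230432	0.001220705181	0.001368420455	0.001280655052	0.001047735803	0.001330693182	0.001556391181	0.001096802138	0.001359886335	0.00124724581	0.001226462402	0.001336728174	0.001268782167
12	0.000954285067	0.0009826250918	0.0008438842069	0.0008460314263	0.0009141836675	0.001052266736	0.001030377279	0.001029637289	0.00107963782	0.0009505766866	0.0009045992012	0.0009412769259	0.0009355979813	0.001030092235	0.0009756657465	0.001039813262	0.0009688997744	0.001045686383	0.0008879344396	0.0009867515559	0.001021726029	0.001048422726	0.0008870152578	0.001020918714	0.0009386637723	0.0009029264209	0.001080948756	0.0009891297646	0.0009928437152	0.001034474458	0.0009218203474
13	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
14	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
15	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
16	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
17	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
18	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
19	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
20	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
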