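curve_id	dose_01	dose_02	dose_03	dose_04	dose_05	dose_06	dose_07	dose_08	dose_09	dose_10
null_000014	1.00406886342863	0.93086546316454	1.03801761708352	0.987613954282354	0.980055047662058	1.00439872931936	1.05042630103486	0.986650116969982	1.00648837813141	1.00156400647978
null_000015	0.997875939858004	0.896326271525851	0.959284421542418	1.04994407571952	1.03121913292193	0.830623276872936	0.981628602795242	1.11416674305216	1.10984954825633	1.01332481915469
reg_000005	0.878142186262235	0.999813966640651	0.935461611305304	0.823596049109517	0.57708324833845	0.406609789838185	0.249887314999905	0.312840675076962	0.270256232154236	0.297368007009716
reg_000006	1.00537255917024	1.00385504397853	0.990919780853288	0.978437345365807	0.887780241166512	0.705608180279487	0.636737699452374	0.631161118825567	0.630582543425433	0.628564733713832
null_000008	1.15170996812477	0.879317314786246	0.995693685785934	0.934318651647064	0.987625401986821	0.893797676561301	1.16717988001094	1.10261033942586	0.997807224604622	1.08738885150089
reg_000004	0.960635245266311	1.03157381033576	0.884737908807108	0.466177518059218	0.450636299486023	0.327542894598335	0.274653189385906	0.289372132879238	0.322945934539823	0.273607744428873
null_000003	1.01356571588731	0.913050190746532	1.24421168287822	1.19796180361366	0.961027688867842	0.85815534547369	0.880286736038202	1.07265447155711	1.21344910883016	1.14802668174576
null_000002	0.969856361485587	0.992101960604351	1.02319603534037	0.967949042238011	1.01850010018197	1.0114482883617	0.97622626005206	0.977935134387102	1.02061755739885	0.992082331214527
null_000001	0.972220498028626	0.959226890495313	1.00000154354362	0.999001020827668	1.00208389606923	1.01720048409816	0.966203744619052	0.987192064873924	0.982100733046364	0.975022225629466
null_000004	1.04030153283699	1.16670181482697	0.932310053869097	0.983116552432042	1.05161789169639	0.901616778591688	0.934966654177127	0.989263387942643	1.0770526432671	1.05981918344028
null_000006	1.04750059433318	1.00624048353482	1.05462725890889	0.94370168910449	1.07681284456132	0.984310249348114	0.991571615718742	0.989344361446637	1.09320339792263	0.915817274069461
null_000009	0.971946999101983	1.0052465741825	0.996377227881251	0.977554502602217	0.939036263610519	0.95964504735172	1.00453438150854	0.988566149093631	1.02960272469061	1.03421336366318
null_000010	1.00456398772985	0.956890489720524	0.961603546953066	1.05569824351982	1.02781326680241	1.0469650654661	0.99636191385987	1.04100355372397	0.957982844486309	0.99174625552623
null_000005	1.0646375023952	0.926689151123784	0.993685710253807	0.974819962416471	0.906078847310064	1.01103113462955	0.965245241620301	1.02775390092242	0.925692336840997	1.0206591215985
null_000018	0.987371836642888	0.987655842380439	0.973543158145746	1.01138675756686	0.966533832877256	1.05158134543476	0.991196328488488	0.976398215876183	1.00116619804871	1.03280852240478
null_000017	0.990060713963463	1.01162203118273	1.01426826065567	0.979674621688645	0.994282164570945	1.02398288097545	1.00789654972519	1.00500052409133	0.98488042619247	0.991880644495363
reg_000001	0.986250674790622	1.2131851782181	2.00673729777914	3.21657824969346	3.65970955905294	3.74737243545051	3.7670782558528	3.73012411231636	3.73310015334479	3.70847537549383
reg_000003	0.891317257330673	1.00154493879347	1.00873104150548	0.98014568510093	1.01088416588646	0.841417814330844	0.567938025604346	0.497267548822258	0.40719123319552	0.503237259730909
reg_000002	1.1262382960063	1.19758278652374	1.41396258644285	1.6058264023547	1.75211065867204	1.75989629133858	1.83903580954408	1.76504491168955	1.80863139006019	1.80854562772371
null_000011	0.955099939845407	0.999806194548297	0.952715072953534	0.981335672347114	1.05137982555883	1.04293490816614	1.05270110536614	0.872231209299414	0.883441573467267	0.712906282604869
null_000013	1.0289630488415	0.905555480534543	0.936305274416808	1.0251176613454	1.0233091752515	1.27936501626485	0.979671552266182	0.958546618720438	0.815550590797529	1.08830081560208
null_000007	0.980796687318184	0.971409188619512	0.991008486579609	0.999851419979142	1.01655348762608	1.00483546622338	0.977006335906977	0.987394997812333	1.01946487101142	0.998966400235547
null_000016	1.01661899563216	1.02760532659488	0.93338898353118	1.22027216499185	1.04531077616012	1.05132693411086	0.802612742090887	0.996499334488451	0.84101499783212	1.06636441203319
null_000012	0.988108813988787	0.958377614525442	0.997138258747648	0.895833708364813	0.999382298081099	1.05700059330488	1.0036363736206	0.95469828022096	1.00476720242165	1.00592533407088
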