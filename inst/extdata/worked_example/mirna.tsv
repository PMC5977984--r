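feature_id	R01	R02	R03	R04	R05	R06	N01	N02	N03	N04	N05	N06
miR-001	12.835492042145557	12.781675559806345	  12.5756907567444	12.571815285319232	12.347537682791232	13.144695590379147	11.452125767426633	11.059874703139899	11.931852528751975	 11.21684715438162	11.269139215694274	11.457466827785378
miR-002	8.9937411186908953	 9.537000373426018	8.9916789119873819	9.1109131640573011	 8.773448699531567	9.4703430876709866	10.549170147651012	 10.68611245995791	 10.31252796767448	10.889926085184419	10.781096072375252	 10.57343554034283
miR-003	7.9232107620442358	7.7333978727922821	7.5100942376141564	7.5337875597894932	 7.618577993846011	7.9321393039948216	8.0183246372839356	7.9389020241177448	7.4087210826738161	7.6756828604683296	8.2134821585755233	8.0960060923216428
miR-004	9.7692621959631314	8.8281888051496917	9.6039700404833859	9.5868346479932107	9.2338009359838615	8.8483726689066842	9.0959710694300533	9.4906581057308461	8.7331623391478974	9.3186021241979624	9.3279299933092172	9.5639266342880234
miR-005	12.152797619607565	 11.66871220801346	12.092078988399283	11.528644182510851	12.269946713037891	11.319505319266138	11.024997903550434	11.627936035821715	12.058790320519531	12.262309325028447	11.975557784719237	12.018465636532923
miR-006	12.174920574610649	12.009437482710819	11.732487131438786	11.926178826888776	11.527088638489046	11.451405797762744	12.067474635399527	11.881547081582269	11.561340265420522	11.242798309369757	11.340109832307567	11.869300451723223
miR-007	6.4821097330776629	6.2598046509138081	6.7347923641588539	6.4169269718758484	   6.7520082622211	6.5698676227420325	 6.837238972475645	6.4610616478383172	6.7200053926516663	6.2227790895525654	6.4174888804975696	6.4450880759356819
miR-008	6.9753426256407076	6.5910343385334125	5.7943518923020108	6.4775605718010736	6.5503578558415301	6.4125431587266419	5.9646015476557714	 6.446058856877495	6.1921372103257974	6.1653975577721711	6.1114185445865008	6.2719162701098901
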