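feature_id	R01	R02	R03	R04	R05	R06	N01	N02	N03	N04	N05	N06
GENE001	8.0703041780273459	 8.090424269263675	  7.80465832533657	8.2116356059274498	8.6439033655946069	6.9743738859985571	9.2022110904618177	 9.612555681369825	8.4670105247866498	9.0178935498398953	9.7184047373089744	9.1961052133292149
GENE002	10.575076012543242	10.043837974987408	10.510698038720136	10.448504274308748	11.116097591766122	 9.840742264370391	11.208161700829349	11.761961713467059	11.442476008510951	  12.2194214296157	11.550918612554607	11.739866622925632
GENE003	  6.46200830051382	6.0382499812600559	 6.675741148272774	5.9549981010169182	7.1584537831614448	6.7929799658649355	7.4801829479400865	 8.248676614858379	6.8742770231968837	7.8080935915671583	7.4185754675040227	7.8193305314375223
GENE004	8.0431432735620305	8.8791129497827619	8.2581181794905163	8.3340076679085495	9.0024671917848043	7.6702960327192145	9.8089654062446829	10.307364139821015	 9.156010984330079	9.9251637486962885	10.027268441322606	9.6647732950602236
GENE005	9.7127213942019459	9.1604993972263742	9.9268272794394168	9.1811272533278636	10.403579617069102	9.2908501522703872	7.9097314785769335	7.7810417631967859	8.5468487821836234	7.6160510096643721	8.0701416125414092	8.7871207113248317
GENE006	9.5524951293344884	9.4350259522172237	9.6631006662890417	9.2194228206883029	9.6229017796760026	9.2037589007587641	8.3084224711579431	7.8902658694363073	8.5629442124136119	 8.134061187629678	7.8325903106199943	8.2288894014901395
GENE007	12.675612333781986	10.875361372991712	12.532521470790087	12.221203604394104	 12.84548758937974	11.959775353522108	10.805427939409761	9.8302598227927209	11.267944334962982	10.442059891666361	10.092698106563793	10.658828372499581
GENE008	 9.924552844997665	9.8143038643076697	9.9173544009274845	10.022673906118664	9.3264112067519704	9.8135979738342343	10.239291556206751	10.332932301165018	9.4596328740631108	10.300947313184622	10.355492703480646	10.411281588581488
GENE009	7.2522527277953808	7.7258337378051758	7.9822698948540332	7.6921959393472381	7.2628899484276941	7.7963882189317344	7.5687806717644452	7.7613464507454566	7.7368564547207086	7.3990123577637048	7.0221487543594598	7.6612185941832811
GENE010	9.4552308977128661	9.3016839901866941	9.6351613983403563	9.8314114337213443	 9.535782200414566	9.3901195081162605	9.3434718482944135	9.7790209800772185	 8.918053933467359	9.4353570838820264	9.4113957981527658	9.9823375098192351
GENE011	6.4856350245606089	6.3095106275370174	6.1440952117293204	6.3351118774351063	6.7937411900742992	 6.384569026912196	6.0641090076147091	5.6468207042079488	6.3475345079125445	5.9900122696819498	5.7458799663441669	6.0657735410430522
GENE012	8.9313115770037879	8.6198902729873979	8.8131420879949314	8.8285974260042668	8.6454962694809367	8.5005714299740713	8.5549902274380596	8.5937304243972825	8.7783983294088088	9.1893316833425303	8.9333500356027997	8.5750720852569575
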