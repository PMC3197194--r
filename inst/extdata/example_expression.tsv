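gene_id	high_001	high_002	high_003	high_004	low_001	low_002	low_003	low_004
SIG001	9.5257052082063964	17.0737579937994823	13.7021620704683684	13.3976762414152883	11.0351056860104997	8.6777131281474382	11.6415956565845544	9.9847303269205074
SIG002	4.0066486611553636	6.3749600872328918	5.9245311722557812	3.6052981812356033	4.3048230168373349	4.8069232927010450	4.0351475848459240	5.2893456181290732
SIG003	8.8620378119898131	12.9688586214051291	9.2568476080419249	8.1441931146383837	6.3421300205122613	7.7127405254258150	8.0745722355290575	7.9101895720916859
SIG004	7.4188284624314660	12.4926913152563550	8.5014746951428108	7.5616029102651989	8.4094781296181331	9.6114417396414886	7.4098601698781099	9.1800833134643209
SIG005	7.7195220813902781	12.3586848146564741	8.3436308818096521	8.7899911784491866	6.0525354361901584	8.6920440608816527	8.8030889733547681	7.7695643582363312
SIG006	8.2877992215738185	12.2708135058569194	8.9957954572769356	9.7159303726983630	7.7861434509837073	6.0158829962528522	8.4315790120582701	9.0205068638614900
SIG007	9.0371672689167362	9.5366352632655484	7.7889594966259654	6.5165060146697753	7.9211885665088841	3.3196609781514166	6.2581690396253453	5.3319635623939377
SIG008	10.7007428137506029	12.5856277569158586	12.6824459077910685	11.2791094822653584	8.5390072844500242	7.2813052028681868	8.5276127075229038	7.6438871022246913
SIG009	10.3489918470111490	14.9481730766243182	14.6814500944081825	11.6345281992641247	10.4116216430291715	9.4302883534194795	13.3036402917691881	12.1055919220382471
SIG010	6.5677812780730722	10.6878198019648920	9.4834171676363859	7.2184510838899687	9.5980381592295068	7.6508555569371106	7.0089193162568915	6.6579708396907904
BG0001	11.0231471622465467	10.2946751749165184	9.1843034204641807	8.7322068305076144	10.3386200782203606	11.0363268802834362	11.3346781081239989	7.7870183892058087
BG0002	11.7793270384004334	10.5650945356014425	8.9695590769280820	9.9992503252918059	9.5703851883579780	11.2717973497307753	10.1338186361308260	9.1190927080187585
BG0003	6.9929306457852167	9.6797920360777283	7.6712606974252324	9.7994284665823468	10.8626916391222164	9.2225710823457501	9.7180704636649899	8.1318189905873659
BG0004	7.9660316263153108	8.2053300759594379	5.1988725101277078	7.3655147635852716	7.8590385231167117	6.7139485169575117	7.2764578506333537	7.6742171544385522
BG0005	9.7672201546959769	9.3413972474497680	8.9004692776374466	9.3035311451538387	7.3436808651374905	8.0924886414702115	6.9386789203419239	7.9969777927183596
BG0006	10.5244679221163349	9.6453231965891266	10.6558135053739882	12.1955164982947171	10.7366397848458970	10.3799947989875037	10.3626104008121995	10.0008405562511413
BG0007	7.3051178453671390	8.0376910515798148	8.0651199368330388	6.0760195402880495	7.3096238383539394	7.1130949458961874	10.6425278370025591	7.5269271257945638
BG0008	8.3999495382967595	10.7148411913837922	9.2903209935623483	8.7040047779113898	10.6690328711369897	10.3809640767172429	10.8472380165765987	10.2321363204394746
BG0009	9.2378378193774946	6.9834095457240766	7.7355926040980361	9.3180243558038853	8.3325367486168176	9.0146340468287267	8.1440497528888027	7.6644191908268686
BG0010	11.6021683816823984	11.9513158077303494	12.9946166606296707	10.2030514665649310	12.8633761499659141	10.7306847345766503	12.1502362811043820	9.7927595443972901
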