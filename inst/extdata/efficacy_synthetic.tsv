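treatment	rr_h2r	rr_h2r_lo	rr_h2r_hi	rr_h2m	rr_h2m_lo	rr_h2m_hi	rr_sae	rr_sae_lo	rr_sae_hi
ETA	2.34065123728942	1.71875680127922	3.18756452951744	1.10353207144653	0.779916212395741	1.56142802695472	1.31543413856998	1.0234709738702	1.69068495061669
IFX	2.41955854499247	1.9062200815352	3.07113727808976	1.12941603790969	0.93637805063519	1.36224955916291	1.77695824792609	1.41504459683468	2.23143540630151
GOL	2.3725306217093	1.90480803068498	2.95510175317989	1.31800074399216	0.992704358909341	1.7498925491497	1.6057041794993	1.36937027985733	1.88282596021445
TCZ	2.14514079666696	1.73603941992643	2.65064778178827	1.26545360432938	0.963955090431417	1.66125252162268	1.14329804498702	0.852285819757217	1.5336761323138
RTX	2.58876798965503	1.86863964731653	3.58641630765277	1.38302971072262	1.05762950847642	1.80854558747794	1.31944045484997	1.01016562357985	1.7234036412021
TOF	2.60792460653465	2.13600857611606	3.18410273695426	1.13552370982943	0.958223838022573	1.34562932419389	1.77799771665595	1.38827354903553	2.27712750317112
BAR	2.32520569686312	1.87106158890265	2.8895796721986	1.16868467427557	0.827488993467063	1.65056439260176	1.28264902483206	0.923168228443364	1.78211128829329
bsIFXr	2.63033365190495	2.25395541472807	3.06956165820091	1.17692449365277	0.932630273388094	1.48520941608275	1.17358660614118	0.963912308085229	1.42887014779377
bsIFXi	2.89539271476679	2.32346833778778	3.60809692836464	1.26475058889482	1.01921100822463	1.56944346087484	1.69682268295437	1.43402790269926	2.00777628661824
bsADA	1.69582949811593	1.34903605414136	2.13177229611594	1.24597125180298	1.02776538249977	1.51050462172951	1.62188815951813	1.17539112939682	2.2379964729996
bsRTX	2.07857510098256	1.70819325239587	2.52926561111565	1.22890984179685	0.937856223314849	1.61028882863014	1.68511934943963	1.33718724816881	2.12358233728636
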