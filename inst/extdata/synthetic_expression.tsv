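gene_id	t0	t30	t60	t90	t120
gene_0001	567.1392741050026	1051.4565260731918	1186.4592982050697	1027.6247216557024	582.9993083797334
gene_0002	498.60143278304884	941.327112975551	1172.9918215484756	861.6657589364748	577.6996962323686
gene_0003	676.7443469566056	750.4899269932935	311.9225758560518	530.47550733306025	660.9112127991723
gene_0004	646.93692533248	947.5901654378325	1221.4330543247734	1006.4837697379143	621.5011942021954
gene_0005	400.5007029266891	205.13509928832804	410.62028595186405	685.2401235817949	373.1728961177288
gene_0006	479.8497788134648	538.1821711197882	551.7456521464618	576.9449954619926	539.6328102867767
gene_0007	0	699.3688501553419	525.1989907179933	287.0119114963818	524.2853010439293
gene_0008	225.80879028423857	554.7703782633739	430.2323936533474	413.95927612167765	432.79818342958924
gene_0009	639.32179946261	1005.4624855018762	1271.3450046845555	933.2056837149621	608.7508084438333
gene_0010	414.4863469962241	298.3063257477006	619.2260374791921	481.17425303246984	311.6490221688854
gene_0011	501.5340630866289	540.628948265448	533.9266544239297	523.915470020986	594.0205449254422
gene_0012	584.5914962718712	939.8388882698082	1199.073635327371	1079.3663308405853	668.4651669457039
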