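channel	SYN1	SYN2	SYN3	SYN4	SYN5	SYN6
A[C>A]A	0.0011901	0.00057599	0.00016543	8e-07	0.00132174	0.00107204
A[C>A]C	2.79e-05	0.00055105	6.261e-05	2.98e-05	0.00089028	0.00146938
A[C>A]G	4.206e-05	0.00179749	0.0002643	0.00059013	0.00159796	0.0001011
A[C>A]T	0.00019529	0.00057983	0.00012795	2.042e-05	0.00159199	5.611e-05
C[C>A]A	0.00088598	0.00105528	9.494e-05	7.41e-06	0.00116017	0
C[C>A]C	0.00030209	8.68e-05	1.68e-05	2.561e-05	0.00073953	1.171e-05
C[C>A]G	0.00035998	0.0007709	0.00057039	6.954e-05	0.00298267	0.09529849
C[C>A]T	0.00104852	0.00074083	2.622e-05	0.00019233	1.139e-05	0.00012699
G[C>A]A	0.00114966	5.703e-05	9.3e-06	6.91e-05	0.00027594	0.00096749
G[C>A]C	0.000424	0.00031493	6.44e-06	0.00296972	5.9e-07	2.362e-05
G[C>A]G	0.0016821	2.16e-05	0.14672341	0.0023764	4.047e-05	1.4e-07
G[C>A]T	0.00020986	0.00097738	6e-08	0.00037333	1.093e-05	8.79e-05
T[C>A]A	6.86e-06	7e-07	1.287e-05	0.09272036	1.221e-05	4.153e-05
T[C>A]C	5.629e-05	0.00075005	1.979e-05	2.918e-05	0.00012564	2.72e-06
T[C>A]G	7.761e-05	0.00020787	1.342e-05	0.00072252	0.0011656	2.583e-05
T[C>A]T	8.009e-05	0.00215219	0.14809616	0.00016742	0.0002813	0.00023697
A[C>G]A	0.00170573	3.24e-06	9.84e-06	0.00026331	0.00033312	0.05200315
A[C>G]C	0.03486627	6.517e-05	3.418e-05	0.0002851	0.00110442	2.364e-05
A[C>G]G	0.10622794	0.16482183	0.00017805	5.13e-06	0	1.655e-05
A[C>G]T	7.64e-06	7.838e-05	3.31e-06	2.13e-06	0.17973344	6.628e-05
C[C>G]A	3.56e-05	7.422e-05	0.00071364	0.00031112	2.239e-05	0.00026207
C[C>G]C	5.2e-06	4e-08	0.11181598	0.00092834	0.06031153	5.767e-05
C[C>G]G	1.506e-05	0.00076128	0.00016585	0.0001864	8.104e-05	0.00041221
C[C>G]T	2e-08	0.00010885	0.00094712	0.00031896	2.71e-06	1.23e-05
G[C>G]A	7.753e-05	0.00019836	5.4e-07	0.00020362	0.00033218	0.00080065
G[C>G]C	4.22e-06	0.00064883	0.00023435	0.00037775	3.1e-07	0.00032686
G[C>G]G	0.00032183	7.21e-06	5.708e-05	0	0.00120932	0.0014009
G[C>G]T	0.29132597	0.00054785	0.00011082	0.08375225	4.207e-05	0.00036691
T[C>G]A	1.634e-05	0.00075126	2.35e-06	4.105e-05	8.2e-07	0.00027173
T[C>G]C	0.000284	7e-08	3.48e-06	0.00074791	0.00041155	5.56e-05
T[C>G]G	1.07e-06	0.00060855	0.00015984	5.552e-05	1.429e-05	9.57e-06
T[C>G]T	0.0652546	0.21524086	0.22576513	1.05e-06	0.00053536	0.00020499
A[C>T]A	0.09384146	5.7e-06	8.425e-05	0.0001407	0.00016483	5e-08
A[C>T]C	3.854e-05	0.00018161	0	1.917e-05	0.17477292	0.0011253
A[C>T]G	7.541e-05	0.00227562	0.00059169	0.00070924	0.00023339	0.00080621
A[C>T]T	4.686e-05	0.00514296	4.36e-06	0.00055463	0.19996508	0.00025918
C[C>T]A	4.7e-07	1.34e-06	0.00081328	0.00023702	0.00025212	0.00213282
C[C>T]C	0.00026171	0.00025095	1.349e-05	0.18230267	0.00025512	1.6e-07
C[C>T]G	0.00062999	5.754e-05	9.346e-05	0.00141642	0.00049757	0.17122727
C[C>T]T	0.03295095	0.00042075	0.00095989	8.977e-05	6e-08	0.00045202
G[C>T]A	0.00239441	1.19e-06	3.706e-05	4e-07	0.00059082	0.00069037
G[C>T]C	0.00060796	0.11881222	2.062e-05	2.039e-05	0.00118029	0.00050804
G[C>T]G	0.00198274	0.0022493	0.0007816	4.856e-05	2.02e-06	3e-07
G[C>T]T	1.3e-05	5.1e-07	0.00055399	3.234e-05	0.00048812	0.0004594
T[C>T]A	0.00103139	0.00044109	4.007e-05	1.986e-05	0.00039135	1.02e-06
T[C>T]C	0.00015433	0.00016051	0.00045068	9.983e-05	0.00013582	0.00116757
T[C>T]G	0.00067706	0.00061313	3e-06	0.22706028	0.0320333	1.489e-05
T[C>T]T	0.00377426	4e-08	9.99e-05	0.00024299	5e-08	9.71e-06
A[T>A]A	0	1.6e-06	0.00013231	0.00179245	0.18731224	0
A[T>A]C	3.354e-05	0.00047374	2.57e-06	6.302e-05	0.00010041	0.0008565
A[T>A]G	1.122e-05	0.000283	0.00017613	6e-08	5.95e-06	1.885e-05
A[T>A]T	0.00031169	0.00106249	0.00016791	7.1e-07	0.0357817	0.00044172
C[T>A]A	0.00044335	0.00045892	0.00026754	0.00094902	0.00040224	0.00106999
C[T>A]C	0.00275929	0.17091174	0.00039571	0.00064068	0.00025927	4.7e-07
C[T>A]G	4.904e-05	1.896e-05	0.00028559	2.1e-06	0.00015535	1.27e-06
C[T>A]T	5.021e-05	2.825e-05	0	0.00079223	2.817e-05	1e-08
G[T>A]A	3.275e-05	6.012e-05	0.00013456	0.00038224	0.00018621	0.03518934
G[T>A]C	1.768e-05	0	1.87e-06	2.21e-05	0.09238095	0.00036666
G[T>A]G	0.0001587	0.00012066	0.00032785	0.0002731	3.382e-05	0.00064428
G[T>A]T	6.562e-05	0.14916614	7.769e-05	0.0462566	1.025e-05	0.1256196
T[T>A]A	5.578e-05	5.25e-06	0.00021397	0.00013249	0.00023909	0.00074917
T[T>A]C	1.543e-05	3.523e-05	6.52e-06	5.04e-06	0.00049874	4.48e-06
T[T>A]G	0.00070546	7.2e-07	0.07177376	1.189e-05	0.00016948	0.22029545
T[T>A]T	0.001438	0.0002375	1.8e-07	2.5e-06	0.00088893	0.00039967
A[T>C]A	0.00075294	8.234e-05	5.974e-05	3.002e-05	8.216e-05	0.00030232
A[T>C]C	0.00026193	0.00040387	2.03e-06	3.225e-05	0.00041275	0.00010119
A[T>C]G	6e-08	2.92e-06	0.12186384	0.00014391	0.00067667	0.00059756
A[T>C]T	0.00010995	0.03386033	0.00020576	0.00027814	3.262e-05	0.0282044
C[T>C]A	3.484e-05	0.00310709	2.106e-05	0.00026072	0.00051506	0.00153688
C[T>C]C	1.19e-06	0.07109407	0.00069612	0.00015901	8.886e-05	0
C[T>C]G	1e-08	0.00028396	3.802e-05	0.00052612	0.00027014	0.23935685
C[T>C]T	3.237e-05	0.00079787	2.954e-05	0.10861743	0.00318457	8.76e-06
G[T>C]A	0.00047373	3.127e-05	0.00013845	2.453e-05	2.19e-06	0.00038935
G[T>C]C	0.18751993	2.622e-05	1.16e-06	0.06262948	0.00244993	9.5e-06
G[T>C]G	0.00339138	0.00143163	7.48e-06	0.00088137	0.00049228	8.982e-05
G[T>C]T	1e-08	0.00101074	0.09127911	0.00123161	0.00114451	0.0005391
T[T>C]A	0	7e-08	5.188e-05	2.948e-05	2.749e-05	0.00022375
T[T>C]C	0.00162865	0.00121756	0.00011662	6.245e-05	0.00016434	8.728e-05
T[T>C]G	0.00102643	0.03162649	0.06655785	0.0001952	0.00023744	0.00011126
T[T>C]T	0.00018027	7.506e-05	7.9e-07	8.39e-05	0.00054109	0.00011245
A[T>G]A	9.87e-06	0.00054539	0.00046256	0.00035155	5.62e-06	0.00117038
A[T>G]C	3.668e-05	2.52e-06	2.61e-06	5.62e-06	0.00041073	0.00095894
A[T>G]G	0.00037367	2.097e-05	5.224e-05	0.16906373	2.54e-06	0.00124841
A[T>G]T	2.28e-06	2.816e-05	3.266e-05	1.51e-06	0	0.00067925
C[T>G]A	0.00038576	0.00158569	2.896e-05	0.00011806	0.00028145	3.8e-07
C[T>G]C	0.00036982	0.00039533	9.17e-06	0.00087318	6.324e-05	3e-08
C[T>G]G	0.00168315	0.00018305	0.00140692	3.939e-05	0.0005916	0.0002498
C[T>G]T	0.00017071	0.00124846	0.00024596	0.00112334	1.4e-07	0.00260298
G[T>G]A	9.539e-05	0.00016921	0.00089435	2e-07	3.33e-06	0.00078811
G[T>G]C	0.00077346	0.00088906	4.51e-06	1e-08	5.27e-06	3.323e-05
G[T>G]G	9.87e-06	0.00020207	7.839e-05	0.00059933	0.00010274	1.9e-07
G[T>G]T	2e-08	0.00068532	5e-08	3.43e-06	0.00010338	5.573e-05
T[T>G]A	0.00068142	0.0001896	0.00017883	0.00039065	0.00045801	2.7e-07
T[T>G]C	2.5e-07	0.00019145	0.00057618	5.033e-05	0.00086901	1.301e-05
T[T>G]G	0.14747456	3.604e-05	8.9e-06	1.465e-05	0.00096879	0.00014445
T[T>G]T	3.73e-06	0.00054151	2.506e-05	1.517e-05	5.345e-05	5.951e-05
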