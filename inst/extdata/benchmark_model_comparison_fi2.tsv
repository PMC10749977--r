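phenotype	clipping	pa_rkhs	pa_rf	mse_rkhs	mse_rf
GM	2	0.857	0.85	0.018	0.018
GM	3	0.87	0.869	0.016	0.017
GM	4	0.894	0.912	0.015	0.013
GM	5	0.866	0.917	0.016	0.012
GM	6	0.863	0.903	0.018	0.012
GM	7	0.844	0.923	0.019	0.01
GM	8	0.881	0.913	0.02	0.015
GM	9	0.897	0.944	0.012	0.008
GM	T	0.867	0.937	0.018	0.009
RG	2	0.868	0.896	0.015	0.014
RG	3	0.94	0.956	0.011	0.008
RG	4	0.859	0.911	0.017	0.012
RG	5	0.826	0.869	0.016	0.013
RG	6	0.833	0.884	0.024	0.016
RG	7	0.862	0.896	0.015	0.011
RG	8	0.86	0.872	0.014	0.013
RG	9	0.813	0.843	0.017	0.014
RG	T	0.886	0.932	0.013	0.008
DM	2	0.537	0.638	0.044	0.035
DM	3	0.802	0.84	0.014	0.013
DM	4	0.935	0.941	0.01	0.009
DM	5	0.882	0.895	0.014	0.015
DM	6	0.884	0.917	0.016	0.011
DM	7	0.849	0.913	0.017	0.011
DM	8	0.911	0.915	0.016	0.016
DM	9	0.787	0.925	0.022	0.011
DM	T	0.912	0.943	0.013	0.009
LDM	2	0.835	0.875	0.019	0.014
LDM	5	0.899	0.924	0.012	0.011
LDM	T	0.9	0.952	0.011	0.007
SDM	2	0.664	0.818	0.033	0.021
SDM	5	0.904	0.921	0.011	0.012
SDM	T	0.694	0.835	0.025	0.015
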