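# synthetic fixture network (generated by circanet::generate_network)
gene_a	gene_b
g0001	g0002
g0001	g0003
g0001	g0064
g0001	g0078
g0001	g0079
g0001	g0080
g0002	g0003
g0002	g0004
g0002	g0005
g0002	g0079
g0002	g0080
g0003	g0004
g0003	g0005
g0003	g0006
g0003	g0080
g0004	g0005
g0004	g0006
g0004	g0007
g0004	g0072
g0005	g0006
g0005	g0007
g0005	g0033
g0006	g0007
g0006	g0008
g0006	g0009
g0007	g0008
g0007	g0009
g0007	g0010
g0008	g0009
g0008	g0010
g0008	g0011
g0009	g0010
g0009	g0011
g0009	g0012
g0010	g0011
g0010	g0012
g0010	g0013
g0010	g0052
g0010	g0063
g0011	g0013
g0011	g0014
g0012	g0013
g0012	g0014
g0012	g0015
g0012	g0040
g0012	g0051
g0013	g0014
g0013	g0015
g0013	g0016
g0014	g0015
g0014	g0016
g0014	g0017
g0014	g0053
g0015	g0017
g0015	g0018
g0016	g0017
g0016	g0018
g0016	g0019
g0016	g0057
g0016	g0058
g0017	g0018
g0017	g0019
g0017	g0020
g0018	g0019
g0018	g0020
g0018	g0021
g0019	g0020
g0019	g0021
g0019	g0022
g0020	g0021
g0020	g0022
g0020	g0023
g0021	g0022
g0021	g0023
g0021	g0024
g0022	g0024
g0022	g0025
g0023	g0024
g0023	g0025
g0023	g0026
g0023	g0045
g0024	g0025
g0024	g0026
g0025	g0027
g0025	g0028
g0025	g0072
g0026	g0027
g0026	g0028
g0026	g0029
g0026	g0036
g0027	g0028
g0027	g0029
g0027	g0030
g0027	g0033
g0027	g0043
g0028	g0029
g0028	g0030
g0028	g0031
g0028	g0049
g0029	g0030
g0029	g0031
g0029	g0032
g0030	g0031
g0030	g0032
g0031	g0032
g0031	g0033
g0031	g0034
g0032	g0033
g0032	g0034
g0032	g0035
g0033	g0034
g0033	g0035
g0033	g0036
g0034	g0035
g0034	g0036
g0034	g0037
g0035	g0036
g0035	g0037
g0035	g0038
g0036	g0037
g0036	g0038
g0036	g0039
g0037	g0038
g0037	g0058
g0037	g0078
g0038	g0039
g0038	g0040
g0038	g0041
g0039	g0040
g0039	g0041
g0039	g0042
g0040	g0041
g0040	g0042
g0041	g0042
g0041	g0043
g0041	g0044
g0042	g0043
g0042	g0044
g0042	g0045
g0042	g0064
g0043	g0044
g0043	g0045
g0043	g0046
g0044	g0045
g0044	g0046
g0045	g0047
g0045	g0048
g0045	g0049
g0045	g0075
g0046	g0047
g0046	g0048
g0046	g0049
g0047	g0048
g0047	g0049
g0047	g0050
g0047	g0073
g0048	g0049
g0048	g0050
g0048	g0051
g0049	g0050
g0049	g0051
g0050	g0051
g0050	g0052
g0050	g0053
g0051	g0052
g0051	g0053
g0051	g0054
g0052	g0053
g0052	g0054
g0052	g0055
g0053	g0054
g0053	g0055
g0054	g0055
g0054	g0056
g0054	g0057
g0054	g0072
g0055	g0056
g0055	g0057
g0055	g0058
g0056	g0057
g0056	g0058
g0056	g0059
g0057	g0059
g0057	g0060
g0058	g0059
g0058	g0060
g0058	g0061
g0059	g0060
g0059	g0061
g0059	g0062
g0060	g0061
g0060	g0062
g0060	g0068
g0061	g0062
g0061	g0063
g0062	g0063
g0062	g0064
g0062	g0065
g0063	g0064
g0063	g0065
g0064	g0066
g0064	g0067
g0064	g0079
g0065	g0066
g0065	g0067
g0065	g0068
g0066	g0067
g0066	g0068
g0066	g0069
g0067	g0068
g0067	g0069
g0067	g0070
g0068	g0069
g0068	g0070
g0068	g0071
g0069	g0070
g0069	g0072
g0069	g0076
g0070	g0071
g0070	g0072
g0070	g0073
g0071	g0072
g0071	g0073
g0071	g0074
g0073	g0075
g0073	g0076
g0074	g0075
g0074	g0076
g0074	g0077
g0075	g0076
g0075	g0077
g0076	g0077
g0076	g0078
g0076	g0079
g0077	g0078
g0077	g0079
g0077	g0080
g0078	g0079
g0078	g0080
g0079	g0080
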