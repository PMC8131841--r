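source	target	mechanism
G00041	G00048	transcription_regulation
G00069	G00010	transcription_regulation
G00047	G00030	binding
G00045	G00035	binding
G00012	G00013	binding
G00045	G00054	binding
G00054	G00007	binding
G00033	G00042	binding
G00035	G00052	binding
G00056	G00019	transcription_regulation
G00014	G00075	transcription_regulation
G00062	G00051	transcription_regulation
G00075	G00044	binding
G00049	G00010	binding
G00029	G00005	binding
G00073	G00014	binding
G00005	G00036	binding
G00076	G00042	transcription_regulation
G00002	G00066	binding
G00038	G00063	transcription_regulation
G00067	G00037	transcription_regulation
G00051	G00016	transcription_regulation
G00009	G00034	binding
G00034	G00071	binding
G00032	G00075	binding
G00061	G00034	transcription_regulation
G00003	G00009	transcription_regulation
G00040	G00061	transcription_regulation
G00009	G00021	transcription_regulation
G00005	G00016	binding
G00039	G00031	binding
G00008	G00061	binding
G00048	G00080	binding
G00008	G00066	transcription_regulation
G00014	G00017	binding
G00035	G00001	transcription_regulation
G00028	G00076	binding
G00038	G00034	binding
G00019	G00063	binding
G00002	G00052	binding
G00026	G00063	binding
G00051	G00032	transcription_regulation
G00061	G00011	binding
G00059	G00032	transcription_regulation
G00041	G00005	binding
G00064	G00026	transcription_regulation
G00041	G00011	transcription_regulation
G00080	G00037	transcription_regulation
G00053	G00037	transcription_regulation
G00011	G00012	binding
G00030	G00068	transcription_regulation
G00066	G00037	binding
G00003	G00007	transcription_regulation
G00053	G00071	binding
G00052	G00078	binding
G00001	G00039	binding
G00073	G00004	binding
G00061	G00059	transcription_regulation
G00075	G00075	binding
G00016	G00075	transcription_regulation
G00056	G00006	transcription_regulation
G00043	G00060	binding
G00051	G00043	binding
G00052	G00070	binding
G00068	G00069	binding
G00019	G00060	transcription_regulation
G00066	G00079	transcription_regulation
G00035	G00042	binding
G00012	G00028	binding
G00044	G00059	binding
G00018	G00062	transcription_regulation
G00039	G00063	transcription_regulation
G00067	G00006	binding
G00056	G00076	binding
G00006	G00032	binding
G00056	G00041	binding
G00002	G00020	binding
G00007	G00078	binding
G00039	G00053	transcription_regulation
G00066	G00077	binding
G00045	G00077	binding
G00060	G00034	transcription_regulation
G00069	G00037	binding
G00039	G00058	transcription_regulation
G00011	G00036	transcription_regulation
G00038	G00066	transcription_regulation
G00005	G00035	binding
G00051	G00031	binding
G00026	G00042	transcription_regulation
G00074	G00033	binding
G00005	G00023	binding
G00025	G00022	transcription_regulation
G00062	G00011	binding
G00037	G00005	transcription_regulation
G00045	G00061	binding
G00076	G00018	binding
G00007	G00018	transcription_regulation
G00018	G00008	binding
G00053	G00068	binding
G00059	G00075	binding
G00050	G00019	binding
G00074	G00060	transcription_regulation
G00053	G00006	binding
G00018	G00001	binding
G00014	G00008	transcription_regulation
G00001	G00076	binding
G00022	G00027	binding
G00052	G00062	transcription_regulation
G00072	G00062	transcription_regulation
G00053	G00002	transcription_regulation
G00063	G00034	binding
G00033	G00034	binding
G00036	G00024	transcription_regulation
G00080	G00063	transcription_regulation
G00036	G00053	transcription_regulation
G00056	G00021	transcription_regulation
G00077	G00007	transcription_regulation
G00036	G00041	transcription_regulation
G00005	G00053	transcription_regulation
G00044	G00036	transcription_regulation
G00020	G00062	transcription_regulation
G00069	G00052	transcription_regulation
G00007	G00039	transcription_regulation
G00070	G00043	binding
G00051	G00043	transcription_regulation
G00008	G00004	binding
G00015	G00003	binding
G00047	G00026	binding
G00018	G00060	binding
G00025	G00077	transcription_regulation
G00008	G00029	binding
G00022	G00011	binding
G00056	G00019	binding
G00028	G00065	binding
G00012	G00035	transcription_regulation
G00050	G00010	binding
G00061	G00038	transcription_regulation
G00041	G00066	binding
G00079	G00023	transcription_regulation
G00027	G00027	transcription_regulation
G00062	G00034	binding
G00078	G00049	transcription_regulation
G00031	G00062	binding
G00072	G00027	binding
G00071	G00073	transcription_regulation
G00011	G00009	binding
G00028	G00053	transcription_regulation
G00051	G00016	transcription_regulation
G00066	G00068	binding
G00064	G00043	transcription_regulation
G00008	G00018	binding
G00032	G00002	binding
G00028	G00058	binding
G00049	G00073	binding
G00080	G00033	transcription_regulation
G00066	G00034	binding
G00068	G00036	transcription_regulation
G00004	G00067	binding
G00045	G00071	binding
G00011	G00031	binding
G00066	G00079	transcription_regulation
G00030	G00029	transcription_regulation
G00063	G00051	transcription_regulation
G00023	G00033	transcription_regulation
G00001	G00047	transcription_regulation
G00012	G00063	binding
G00023	G00007	transcription_regulation
G00005	G00043	transcription_regulation
G00012	G00055	transcription_regulation
G00059	G00011	binding
G00058	G00063	transcription_regulation
G00044	G00067	binding
G00030	G00033	transcription_regulation
G00002	G00006	binding
G00015	G00051	binding
G00014	G00035	binding
G00067	G00013	transcription_regulation
G00048	G00047	transcription_regulation
G00057	G00002	binding
G00005	G00050	transcription_regulation
G00033	G00044	binding
G00062	G00051	transcription_regulation
G00053	G00033	binding
G00029	G00046	binding
G00024	G00015	binding
G00015	G00079	binding
G00014	G00078	binding
G00038	G00025	transcription_regulation
G00001	G00055	binding
G00008	G00044	transcription_regulation
G00059	G00004	transcription_regulation
G00016	G00039	transcription_regulation
G00004	G00015	binding
G00069	G00057	binding
G00028	G00005	transcription_regulation
G00076	G00058	transcription_regulation
G00003	G00028	binding
G00013	G00030	transcription_regulation
G00072	G00009	binding
G00020	G00016	binding
G00050	G00022	binding
G00035	G00005	transcription_regulation
G00022	G00023	binding
G00076	G00055	binding
G00038	G00035	binding
G00007	G00041	transcription_regulation
G00004	G00062	binding
G00063	G00007	transcription_regulation
G00011	G00063	transcription_regulation
G00063	G00019	transcription_regulation
G00031	G00029	transcription_regulation
G00033	G00019	binding
G00014	G00011	binding
G00032	G00064	binding
G00018	G00078	transcription_regulation
G00025	G00077	transcription_regulation
G00028	G00047	binding
G00052	G00035	transcription_regulation
G00045	G00005	transcription_regulation
G00038	G00037	binding
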