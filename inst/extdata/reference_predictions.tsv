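# Published actual vs predicted pIC50 of the two 3D-QSAR models, verbatim.
# Regression fixtures only, never training input. Residual convention of
# the consistent CoMFA columns: res = pred - actual. The CoMSIA residual
# column is internally inconsistent in the source table and is retained
# verbatim for the record, not used as a fixture.
compound_no	actual	comfa_pred	comfa_res	comsia_pred	comsia_res
1	6.8861	6.758	-0.1281	6.899	0.141
2	6.6778	6.752	0.0742	6.64	-0.112
3	4.5229	4.821	0.2981	4.749	-0.072
4	6.4685	6.201	-0.2675	6.153	-0.048
5	4.5229	4.891	0.3681	4.921	0.03
6	6.2441	6.123	-0.1211	6.411	0.288
7	6.4089	6.335	-0.0739	6.33	-0.005
8	6.9586	6.771	-0.1876	7.003	0.232
9	6.1308	6.237	0.1062	5.89	-0.347
10	6.0132	6.062	0.0488	5.964	-0.098
11	6.7959	6.211	-0.5849	6.312	0.101
12	5.9101	5.578	-0.3321	5.563	-0.015
13	6.0315	6.732	0.7005	6.542	-0.19
14	6.1612	6.09	-0.0712	6.002	-0.088
15	5.5513	6.085	0.5337	6.001	-0.084
16	5.0605	5.225	0.1645	5.093	-0.132
17	6.7212	6.544	-0.1772	6.523	-0.021
18	5.4841	5.154	-0.3301	5.341	0.187
19	6.6021	6.66	0.0579	6.614	-0.046
20	6.9586	7.05	0.0914	7.059	0.009
21	6.5229	6.456	-0.0669	6.816	0.36
22	5.6402	5.597	-0.0432	5.674	0.077
23	5.058	5.066	0.008	5.122	0.056
24	5.4841	5.19	-0.2941	5.295	0.105
25	4.7622	5.112	0.3498	5.178	0.066
26	6.7447	6.765	0.0203	6.944	0.179
27	5.4895	5.126	-0.3635	5.272	0.146
28	5.6655	5.579	-0.0865	5.481	-0.098
29	7	6.983	-0.017	6.971	-0.012
30	5.1643	5.196	0.0317	5.171	-0.025
31	6.6021	6.977	0.3749	6.959	-0.018
32	6.2147	6.396	0.1813	6.076	-0.32
33	6.8861	6.805	-0.0811	6.934	0.129
34	7	6.861	-0.139	7.047	0.186
35	6.8239	6.768	-0.0559	6.802	0.034
36	6.5229	6.599	0.0761	6.565	-0.034
37	4.7857	5.214	0.4283	5.204	-0.01
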