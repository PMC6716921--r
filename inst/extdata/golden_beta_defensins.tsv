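id	length	mw	spacing	charge	pi
VkBD1	41	4816.46	6-3-9-6	4.5	7.9826
VkBD2	44	4770.49	6-4-9-6	4.0	8.5177
VkBD3	68	7510.69	6-4-9-6	-1.0	5.635
VkBD4	48	5466.13	6-4-9-6	-0.5	6.1876
VkBD5	45	5112.8	6-4-9-6	4.5	8.5056
VkBD6	70	7548.7	6-4-9-7-7-5	4.5	7.9825
VkBD7	83	8922.43	6-6-8-5/6-6-7-5	6.0	8.2233
VkBD8	39	3850.54	6-6-7-5	2.5	7.9391
VkBD9	46	5087.15	6-6-9-5	7.5	9.7437
VkBD10	49	5346.37	6-6-7-5	0.5	6.8341
VkBD11	40	4130.68	6-7-9-5	-5.0	3.8346
VkBD12	61	7362.5	6-6-12-7	6.0	9.0239
VkBD13	56	6373.34	6-6-12-7	2.0	7.9229
VkBD14	53	6051.22	6-6-12-7	9.5	10.3828
VkBD15	42	4598.66	6-6-9-6	9.5	10.246
VkBD16	54	5598.25	6-2-3-10-3-3	2.0	7.796
VkBD17	47	5538.28	6-2-3-9-3-3	6.0	8.4828
VkBD18	50	5606.31	6-2-3-10-3-3	2.5	7.512
VkBD19	52	5871.76	7-6-10-7	-0.5	5.6992
VkBD20	43	4861.77	1-3-9-7	2.0	7.9237
VkBD21	38	4009.73	6-4-9-5	6.5	9.1233
VkBD22	42	4645.55	6-4-9-5	4.5	8.5176
VkBD23	104	11026.09	6-4-9-6	-3.0	4.6839
VkBD24	48	5012.86	7-4-9-6	3.5	8.2461
VkBD25	42	4575.41	6-4-9-5	3.5	8.2423
VkBD26	44	4914.62	6-4-11-5	-3.0	4.2446
VkBD27	41	4535.29	6-4-10-5	7.0	9.6914
VkBD28	45	4618.16	6-4-9-6	0.0	5.9979
VkBD29	44	4958.8	6-7-9-5	4.5	8.5135
VkBD30	44	4538.29	6-8-9-5	0.0	6.0306
VkBD31	44	5009.92	6-7-10-5	3.0	8.1509
VkBD32	41	4339.01	6-4-9-5	3.5	8.1572
VkBD33	44	4782.74	6-4-9-5	8.5	10.5052
VkBD34	84	9330.95	7-4-9-5/7-4-9-5	4.5	8.0587
VkBD35	47	5058.7	6-5-9-5	-5.0	3.9254
VkBD36	48	5026.65	6-5-9-5	-8.0	3.371
VkBD37	43	4702.36	6-4-9-5	-1.0	4.7382
VkBD38	44	5172.09	6-4-10-6	2.5	7.9416
VkBD39	111	11483.56	6-4-9-5/6-4-9-5/6-4-9-5	5.0	7.86
VkBD40	43	4914.68	6-4-9-5	2.5	7.9327
VkBD41	41	4641.48	6-4-8-5	3.5	7.9625
VkBD42	42	4717.47	6-4-8-5	5.5	8.8017
VkBD43	74	7874.1	6-4-9-5/6-4-9-5	2.5	7.65
VkBD44	45	5073.96	6-4-9-5	5.0	8.5147
VkBD45	38	4229.98	6-3-9-5	8.0	9.7441
VkBD46	40	4388.17	6-4-9-5	9.5	10.8323
VkBD47	44	5072.96	6-4-10-5	6.5	9.154
VkBD48	52	5934.01	6-4-9-5	13.0	11.9504
VkBD49	40	4566.32	6-4-9-5	5.5	8.814
VkBD50	42	4627.4	6-4-9-5	7.0	10.4698
VkBD51	40	4467.32	6-4-9-5	9.0	11.3419
VkBD52	40	4623.65	6-4-9-5	8.0	11.1693
VkBD53	40	4537.41	6-4-9-5	10.0	11.9738
VkBD54	42	4760.65	6-4-9-5	11.0	12.1412
VkBD55	56	6092.22	6-2-9-6	6.5	8.7963
VkBD56	44	5031.94	3-4-8-5	8.5	9.2085
VkBD57	40	4852.66	6-4-9-5	8.5	9.9206
VkBD58	44	5254.16	6-7-8-5	6.5	8.8379
VkBD59	40	4369.02	6-4-9-5	5.5	8.6986
VkBD60	44	5232.0	6-4-10-5	6.5	8.6105
VkBD61	44	5146.91	6-4-9-6	7.0	9.5242
VkBD62	43	4829.59	3-10-16-6	7.5	9.1865
VkBD79	49	5260.29	6-4-9-6	4.0	8.2526
VkBD80a	45	5112.96	6-4-9-6	5.5	8.5212
VkBD80b	45	5166.0	6-4-9-6	6.5	9.0493
VkBDic1	44	5069.05	6-4-9-5	10.0	10.3026
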