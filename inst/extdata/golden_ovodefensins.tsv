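id	length	mw	spacing	charge	pi
VkOVOD1	45	4930.77	9-2-4-8-1-4	4.0	8.0905
VkOVOD2	49	5582.3	6-3-13-6	4.0	8.5149
VkOVOD3	48	4950.69	5-6-12-3-1-6	8.5	8.9348
VkOVOD4	40	4271.9	3-3-3-9-1-6	4.5	8.0913
VkOVOD5	53	5869.76	14-6-13-2	1.5	7.5215
VkOVOD6	38	4252.89	3-3-3-9-1-6	3.0	7.8246
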