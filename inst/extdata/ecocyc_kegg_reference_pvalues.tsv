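label	k	p_fine	p_fine_corrected	p_coarse	p_coarse_corrected
cysteine	3	4.6e-9	1.6e-6	7.5e-6	8.9e-4
cysteine	2	5.0e-6	1.8e-3	3.9e-4	4.7e-2
cysteine	1	2.7e-3	9.7e-1	2.0e-2	1.0
arginine	12	1.7e-28	6.0e-26	1.8e-26	2.1e-24
arginine	11	1.8e-25	6.5e-23	4.2e-24	5.0e-22
arginine	10	1.0e-22	3.5e-20	8.8e-22	1.0e-19
arginine	9	3.6e-20	1.3e-17	1.6e-19	1.9e-17
arginine	8	9.8e-18	3.5e-15	2.7e-17	3.3e-15
arginine	7	2.1e-15	7.6e-13	4.2e-15	5.0e-13
arginine	6	3.9e-13	1.4e-10	5.9e-13	7.0e-11
arginine	5	6.1e-11	2.1e-8	7.6e-11	9.0e-9
arginine	4	8.3e-9	2.9e-6	9.1e-9	1.1e-6
arginine	3	1.0e-6	3.6e-4	1.0e-6	1.2e-4
arginine	2	1.1e-4	3.9e-2	1.1e-4	1.3e-2
arginine	1	1.1e-2	1.0	1.1e-2	1.0
selenocysteine	4	1.7e-11	5.9e-9	7.2e-9	8.5e-7
selenocysteine	3	1.8e-8	6.5e-6	8.5e-7	1.0e-4
selenocysteine	2	1.0e-5	3.5e-3	9.6e-5	1.1e-2
selenocysteine	1	3.6e-3	1.0	1.0e-2	1.0
valine	9	1.6e-22	5.8e-20	3.9e-20	4.6e-18
valine	8	1.8e-19	6.3e-17	8.1e-18	9.6e-16
valine	7	9.7e-17	3.4e-14	1.5e-15	1.8e-13
valine	6	3.5e-14	1.3e-11	2.5e-13	3.0e-11
valine	5	9.6e-12	3.4e-9	3.9e-11	4.6e-9
valine	4	2.1e-9	7.5e-7	5.4e-9	6.5e-7
valine	3	3.8e-7	1.4e-4	7.0e-7	8.4e-5
valine	2	6.0e-5	2.1e-2	8.4e-5	1.0e-2
valine	1	8.2e-3	1.0	9.4e-3	1.0
purine	10	1.51e-24	5.35e-22	2.53e-14	3.01e-12
purine	9	1.64e-21	5.82e-19	6.14e-13	7.31e-11
purine	8	8.94e-19	3.16e-16	1.47e-11	1.75e-9
purine	7	3.25e-16	1.15e-13	3.48e-10	4.14e-8
purine	6	8.84e-14	3.13e-11	8.12e-9	9.67e-7
purine	5	1.93e-11	6.83e-9	1.87e-7	2.23e-5
purine	4	3.51e-9	1.24e-6	4.25e-6	5.06e-4
purine	3	5.48e-7	1.94e-4	9.54e-5	1.14e-2
purine	2	7.50e-5	2.65e-2	2.11e-3	2.52e-1
purine	1	9.12e-3	1.00	4.63e-2	1.00
pyrimidine	13	2.03e-30	7.19e-28	3.49e-21	4.16e-19
pyrimidine	12	2.20e-27	7.79e-25	1.50e-19	1.78e-17
pyrimidine	11	1.19e-24	4.23e-22	6.28e-18	7.47e-16
pyrimidine	10	4.32e-22	1.53e-19	2.57e-16	3.05e-14
pyrimidine	9	1.18e-19	4.16e-17	1.02e-14	1.22e-12
pyrimidine	8	2.56e-17	9.05e-15	4.00e-13	4.76e-11
pyrimidine	7	4.64e-15	1.64e-12	1.53e-11	1.82e-9
pyrimidine	6	7.23e-13	2.56e-10	5.70e-10	6.78e-8
pyrimidine	5	9.86e-11	3.49e-8	2.08e-8	2.48e-6
pyrimidine	4	1.20e-8	4.23e-6	7.45e-7	8.86e-5
pyrimidine	3	1.31e-6	4.63e-4	2.61e-5	3.11e-3
pyrimidine	2	1.30e-4	4.60e-2	8.98e-4	1.07e-1
pyrimidine	1	1.19e-2	1.00	3.02e-2	1.00
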