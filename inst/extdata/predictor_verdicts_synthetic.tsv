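gene	hgvs_c	tool	verdict
APP	c.2229C>T	MUTATIONTASTER	DAMAGING
APP	c.2229C>T	CADD	TOLERATED
APP	c.2229C>T	FATHMM_XF	TOLERATED
PSEN1	c.253C>T	POLYPHEN2	DAMAGING
PSEN1	c.253C>T	MCAP	DAMAGING
PSEN1	c.253C>T	CADD	DAMAGING
PSEN1	c.253C>T	MUTATIONTASTER	DAMAGING
CCNF	c.353T>C	POLYPHEN2	DAMAGING
CCNF	c.353T>C	MCAP	DAMAGING
CCNF	c.353T>C	CADD	DAMAGING
CCNF	c.353T>C	MUTATIONTASTER	DAMAGING
CCNF	c.656T>C	POLYPHEN2	DAMAGING
CCNF	c.656T>C	MCAP	DAMAGING
CCNF	c.656T>C	CADD	DAMAGING
CCNF	c.656T>C	MUTATIONTASTER	DAMAGING
CSF1R	c.1400C>T	POLYPHEN2	DAMAGING
CSF1R	c.1400C>T	MCAP	TOLERATED
CSF1R	c.1400C>T	CADD	TOLERATED
CSF1R	c.1400C>T	MUTATIONTASTER	TOLERATED
CSF1R	c.1477A>G	POLYPHEN2	DAMAGING
CSF1R	c.1477A>G	MCAP	TOLERATED
CSF1R	c.1477A>G	CADD	TOLERATED
CSF1R	c.1477A>G	MUTATIONTASTER	TOLERATED
CSF1R	c.2850C>A	POLYPHEN2	DAMAGING
CSF1R	c.2850C>A	MCAP	TOLERATED
CSF1R	c.2850C>A	CADD	TOLERATED
CSF1R	c.2850C>A	MUTATIONTASTER	TOLERATED
CSF1R	c.2851C>A	POLYPHEN2	DAMAGING
CSF1R	c.2851C>A	MCAP	TOLERATED
CSF1R	c.2851C>A	CADD	TOLERATED
CSF1R	c.2851C>A	MUTATIONTASTER	TOLERATED
DCTN1	c.1361T>C	POLYPHEN2	DAMAGING
DCTN1	c.1361T>C	MCAP	DAMAGING
DCTN1	c.1361T>C	CADD	DAMAGING
DCTN1	c.1361T>C	MUTATIONTASTER	DAMAGING
DCTN1	c.1555A>G	POLYPHEN2	DAMAGING
DCTN1	c.1555A>G	MCAP	DAMAGING
DCTN1	c.1555A>G	CADD	DAMAGING
DCTN1	c.1555A>G	MUTATIONTASTER	DAMAGING
NOTCH3	c.3315C>T	MUTATIONTASTER	DAMAGING
NOTCH3	c.3315C>T	CADD	TOLERATED
NOTCH3	c.3315C>T	FATHMM_XF	TOLERATED
NOTCH3	c.3535A>G	POLYPHEN2	DAMAGING
NOTCH3	c.3535A>G	MCAP	DAMAGING
NOTCH3	c.3535A>G	CADD	DAMAGING
NOTCH3	c.3535A>G	MUTATIONTASTER	DAMAGING
NOTCH3	c.4461C>T	MUTATIONTASTER	DAMAGING
NOTCH3	c.4461C>T	CADD	TOLERATED
NOTCH3	c.4461C>T	FATHMM_XF	TOLERATED
NOTCH3	c.5816-6C>T	NETGENE2	DAMAGING
NOTCH3	c.5816-6C>T	MAXENTSCAN	TOLERATED
NOTCH3	c.5816-6C>T	HSF	TOLERATED
OPTN	c.448C>T	MUTATIONTASTER	DAMAGING
OPTN	c.448C>T	CADD	TOLERATED
OPTN	c.448C>T	FATHMM_XF	TOLERATED
SQSTM1	c.315C>T	MUTATIONTASTER	DAMAGING
SQSTM1	c.315C>T	CADD	TOLERATED
SQSTM1	c.315C>T	FATHMM_XF	TOLERATED
SQSTM1	c.960G>A	MUTATIONTASTER	DAMAGING
SQSTM1	c.960G>A	CADD	TOLERATED
SQSTM1	c.960G>A	FATHMM_XF	TOLERATED
ABCA7	c.2476G>A	POLYPHEN2	DAMAGING
ABCA7	c.2476G>A	MCAP	DAMAGING
ABCA7	c.2476G>A	CADD	DAMAGING
ABCA7	c.2476G>A	MUTATIONTASTER	DAMAGING
ABCA7	c.2629G>A	POLYPHEN2	DAMAGING
ABCA7	c.2629G>A	MCAP	TOLERATED
ABCA7	c.2629G>A	CADD	TOLERATED
ABCA7	c.2629G>A	MUTATIONTASTER	TOLERATED
ABCA7	c.3412A>C	POLYPHEN2	DAMAGING
ABCA7	c.3412A>C	MCAP	DAMAGING
ABCA7	c.3412A>C	CADD	DAMAGING
ABCA7	c.3412A>C	MUTATIONTASTER	DAMAGING
ABCA7	c.3472+5G>C	NETGENE2	DAMAGING
ABCA7	c.3472+5G>C	MAXENTSCAN	TOLERATED
ABCA7	c.3472+5G>C	HSF	TOLERATED
ABCA7	c.4343G>A	POLYPHEN2	DAMAGING
ABCA7	c.4343G>A	MCAP	TOLERATED
ABCA7	c.4343G>A	CADD	TOLERATED
ABCA7	c.4343G>A	MUTATIONTASTER	TOLERATED
SORL1	c.133G>T	POLYPHEN2	DAMAGING
SORL1	c.133G>T	MCAP	DAMAGING
SORL1	c.133G>T	CADD	DAMAGING
SORL1	c.133G>T	MUTATIONTASTER	DAMAGING
SORL1	c.6150A>G	MUTATIONTASTER	DAMAGING
SORL1	c.6150A>G	CADD	TOLERATED
SORL1	c.6150A>G	FATHMM_XF	TOLERATED
ADAM10	c.112A>G	POLYPHEN2	DAMAGING
ADAM10	c.112A>G	MCAP	TOLERATED
ADAM10	c.112A>G	CADD	TOLERATED
ADAM10	c.112A>G	MUTATIONTASTER	TOLERATED
ADAM10	c.556dupC	POLYPHEN2	DAMAGING
ADAM10	c.556dupC	MCAP	DAMAGING
ADAM10	c.556dupC	CADD	DAMAGING
ADAM10	c.556dupC	MUTATIONTASTER	DAMAGING
BIN1	c.865G>A	POLYPHEN2	DAMAGING
BIN1	c.865G>A	MCAP	TOLERATED
BIN1	c.865G>A	CADD	TOLERATED
BIN1	c.865G>A	MUTATIONTASTER	TOLERATED
CLU	c.509C>T	POLYPHEN2	DAMAGING
CLU	c.509C>T	MCAP	TOLERATED
CLU	c.509C>T	CADD	TOLERATED
CLU	c.509C>T	MUTATIONTASTER	TOLERATED
CR1	c.4956G>A	MUTATIONTASTER	DAMAGING
CR1	c.4956G>A	CADD	TOLERATED
CR1	c.4956G>A	FATHMM_XF	TOLERATED
CR1	c.4356T>C	MUTATIONTASTER	DAMAGING
CR1	c.4356T>C	CADD	TOLERATED
CR1	c.4356T>C	FATHMM_XF	TOLERATED
ELAVL1	c.765C>T	MUTATIONTASTER	DAMAGING
ELAVL1	c.765C>T	CADD	TOLERATED
ELAVL1	c.765C>T	FATHMM_XF	TOLERATED
EP300	c.2194C>T	POLYPHEN2	DAMAGING
EP300	c.2194C>T	MCAP	DAMAGING
EP300	c.2194C>T	CADD	DAMAGING
EP300	c.2194C>T	MUTATIONTASTER	DAMAGING
EPHA1	c.928A>G	POLYPHEN2	DAMAGING
EPHA1	c.928A>G	MCAP	TOLERATED
EPHA1	c.928A>G	CADD	TOLERATED
EPHA1	c.928A>G	MUTATIONTASTER	TOLERATED
FERMT2	c.1077G>C	MUTATIONTASTER	DAMAGING
FERMT2	c.1077G>C	CADD	TOLERATED
FERMT2	c.1077G>C	FATHMM_XF	TOLERATED
FERMT2	c.1538C>T	POLYPHEN2	DAMAGING
FERMT2	c.1538C>T	MCAP	DAMAGING
FERMT2	c.1538C>T	CADD	DAMAGING
FERMT2	c.1538C>T	MUTATIONTASTER	DAMAGING
INPP5D	c.470G>A	POLYPHEN2	DAMAGING
INPP5D	c.470G>A	MCAP	DAMAGING
INPP5D	c.470G>A	CADD	DAMAGING
INPP5D	c.470G>A	MUTATIONTASTER	DAMAGING
INPP5D	c.2085C>T	MUTATIONTASTER	DAMAGING
INPP5D	c.2085C>T	CADD	TOLERATED
INPP5D	c.2085C>T	FATHMM_XF	TOLERATED
MARK2	c.1611C>T	MUTATIONTASTER	DAMAGING
MARK2	c.1611C>T	CADD	TOLERATED
MARK2	c.1611C>T	FATHMM_XF	TOLERATED
MARK4	c.1553C>T	POLYPHEN2	DAMAGING
MARK4	c.1553C>T	MCAP	TOLERATED
MARK4	c.1553C>T	CADD	TOLERATED
MARK4	c.1553C>T	MUTATIONTASTER	TOLERATED
PICALM	c.1231G>C	POLYPHEN2	DAMAGING
PICALM	c.1231G>C	MCAP	DAMAGING
PICALM	c.1231G>C	CADD	DAMAGING
PICALM	c.1231G>C	MUTATIONTASTER	DAMAGING
PLCG2	c.3379C>A	POLYPHEN2	DAMAGING
PLCG2	c.3379C>A	MCAP	DAMAGING
PLCG2	c.3379C>A	CADD	DAMAGING
PLCG2	c.3379C>A	MUTATIONTASTER	DAMAGING
PLCG2	c.408G>A	MUTATIONTASTER	DAMAGING
PLCG2	c.408G>A	CADD	TOLERATED
PLCG2	c.408G>A	FATHMM_XF	TOLERATED
RIN3	c.2377T>C	POLYPHEN2	DAMAGING
RIN3	c.2377T>C	MCAP	DAMAGING
RIN3	c.2377T>C	CADD	DAMAGING
RIN3	c.2377T>C	MUTATIONTASTER	DAMAGING
TOMM40	c.384C>G	POLYPHEN2	DAMAGING
TOMM40	c.384C>G	MCAP	TOLERATED
TOMM40	c.384C>G	CADD	TOLERATED
TOMM40	c.384C>G	MUTATIONTASTER	TOLERATED
ZCWPW1	c.1834C>T	MUTATIONTASTER	DAMAGING
ZCWPW1	c.1834C>T	CADD	TOLERATED
ZCWPW1	c.1834C>T	FATHMM_XF	TOLERATED
ZCWPW1	c.314A>G	POLYPHEN2	DAMAGING
ZCWPW1	c.314A>G	MCAP	DAMAGING
ZCWPW1	c.314A>G	CADD	DAMAGING
ZCWPW1	c.314A>G	MUTATIONTASTER	DAMAGING
ZCWPW1	c.283-5T>G	NETGENE2	DAMAGING
ZCWPW1	c.283-5T>G	MAXENTSCAN	TOLERATED
ZCWPW1	c.283-5T>G	HSF	TOLERATED
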