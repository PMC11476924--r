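symbol	family	role	elr_positive	aliases	mouse_homolog
CXCL1	CXC	ligand	TRUE	GRO-alpha	Cxcl1
CXCL2	CXC	ligand	TRUE	GRO-beta	Cxcl2
CXCL3	CXC	ligand	TRUE	GRO-gamma	Cxcl3
PF4	CXC	ligand	FALSE	CXCL4	Pf4
CXCL5	CXC	ligand	TRUE	ENA-78	Cxcl5
CXCL6	CXC	ligand	TRUE	GCP-2	
PPBP	CXC	ligand	TRUE	CXCL7	Ppbp
CXCL8	CXC	ligand	TRUE	IL8	
CXCL9	CXC	ligand	FALSE	MIG	Cxcl9
CXCL10	CXC	ligand	FALSE	IP-10	Cxcl10
CXCL11	CXC	ligand	FALSE	I-TAC	Cxcl11
CXCL12	CXC	ligand	FALSE	SDF-1	Cxcl12
CXCL13	CXC	ligand	FALSE	BCA-1	Cxcl13
CXCL14	CXC	ligand	FALSE	BRAK	Cxcl14
CXCL16	CXC	ligand	FALSE		Cxcl16
CCL1	CC	ligand	FALSE	I-309	Ccl1
CCL2	CC	ligand	FALSE	MCP-1	Ccl2
CCL3	CC	ligand	FALSE	MIP-1-alpha	Ccl3
CCL4	CC	ligand	FALSE	MIP-1-beta	Ccl4
CCL5	CC	ligand	FALSE	RANTES	Ccl5
CCL7	CC	ligand	FALSE	MCP-3	Ccl7
CCL8	CC	ligand	FALSE	MCP-2	Ccl8
CCL11	CC	ligand	FALSE	eotaxin	Ccl11
CCL13	CC	ligand	FALSE	MCP-4	
CCL14	CC	ligand	FALSE	HCC-1	
CCL15	CC	ligand	FALSE	HCC-2	
CCL16	CC	ligand	FALSE	HCC-4	
CCL18	CC	ligand	FALSE	PARC	
CCL19	CC	ligand	FALSE	ELC	Ccl19
CCL20	CC	ligand	FALSE	MIP-3-alpha	Ccl20
CCL21	CC	ligand	FALSE	SLC	Ccl21a
CCL22	CC	ligand	FALSE	MDC	Ccl22
CCL23	CC	ligand	FALSE	MPIF-1	
CCL24	CC	ligand	FALSE	eotaxin-2	Ccl24
CCL26	CC	ligand	FALSE	eotaxin-3	Ccl26
CCL28	CC	ligand	FALSE	MEC	Ccl28
XCL1	XC	ligand	FALSE	lymphotactin	Xcl1
XCL2	XC	ligand	FALSE	SCM-1-beta	
CX3CL1	CX3C	ligand	FALSE	fractalkine	Cx3cl1
CXCR1	CXC	receptor	FALSE	IL8RA	Cxcr1
CXCR2	CXC	receptor	FALSE	IL8RB	Cxcr2
CXCR3	CXC	receptor	FALSE		Cxcr3
CXCR4	CXC	receptor	FALSE		Cxcr4
CXCR5	CXC	receptor	FALSE	BLR1	Cxcr5
CXCR6	CXC	receptor	FALSE	BONZO	Cxcr6
CCR1	CC	receptor	FALSE		Ccr1
CCR2	CC	receptor	FALSE		Ccr2
CCR3	CC	receptor	FALSE		Ccr3
CCR4	CC	receptor	FALSE		Ccr4
CCR5	CC	receptor	FALSE		Ccr5
CCR6	CC	receptor	FALSE		Ccr6
CCR7	CC	receptor	FALSE		Ccr7
CCR8	CC	receptor	FALSE		Ccr8
CCR9	CC	receptor	FALSE		Ccr9
CCR10	CC	receptor	FALSE	GPR2	Ccr10
XCR1	XC	receptor	FALSE	GPR5	Xcr1
CX3CR1	CX3C	receptor	FALSE		Cx3cr1
ACKR1	CXC	receptor	FALSE	DARC	Ackr1
ACKR2	CC	receptor	FALSE	D6	Ackr2
ACKR3	CXC	receptor	FALSE	CXCR7	Ackr3
ACKR4	CC	receptor	FALSE	CCRL1	Ackr4
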