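pt_id	pt_name	hlgt_id	hlgt_name	soc_id	soc_name
PT0016	Nausea	HLGT0005	Gastrointestinal motility and defaecation conditions	SOC0002	Gastrointestinal disorders
PT0030	Vomiting	HLGT0005	Gastrointestinal motility and defaecation conditions	SOC0002	Gastrointestinal disorders
PT0009	Headache	HLGT0009	Neurological disorders NEC	SOC0007	Nervous system disorders
PT0007	Dizziness	HLGT0009	Neurological disorders NEC	SOC0007	Nervous system disorders
PT0025	Somnolence	HLGT0009	Neurological disorders NEC	SOC0007	Nervous system disorders
PT0006	Confusional state	HLGT0009	Neurological disorders NEC	SOC0007	Nervous system disorders
PT0018	Paraesthesia	HLGT0011	Peripheral neuropathies	SOC0007	Nervous system disorders
PT0010	Hypoaesthesia	HLGT0011	Peripheral neuropathies	SOC0007	Nervous system disorders
PT0017	Neurotoxicity	HLGT0011	Peripheral neuropathies	SOC0007	Nervous system disorders
PT0023	Seizure	HLGT0014	Seizures (including subtypes)	SOC0007	Nervous system disorders
PT0014	Monoplegia	HLGT0010	Neuromuscular disorders	SOC0007	Nervous system disorders
PT0015	Muscular weakness	HLGT0010	Neuromuscular disorders	SOC0007	Nervous system disorders
PT0019	Phrenic nerve paralysis	HLGT0010	Neuromuscular disorders	SOC0007	Nervous system disorders
PT0027	Tremor	HLGT0007	Movement disorders	SOC0007	Nervous system disorders
PT0011	Hypotension	HLGT0003	Decreased and nonspecific blood pressure disorders and shock	SOC0001	Cardiac disorders
PT0026	Tachycardia	HLGT0002	Cardiac arrhythmias	SOC0001	Cardiac disorders
PT0004	Bradycardia	HLGT0002	Cardiac arrhythmias	SOC0001	Cardiac disorders
PT0024	Sinus tachycardia	HLGT0002	Cardiac arrhythmias	SOC0001	Cardiac disorders
PT0029	Ventricular fibrillation	HLGT0002	Cardiac arrhythmias	SOC0001	Cardiac disorders
PT0005	Cardiac arrest	HLGT0002	Cardiac arrhythmias	SOC0001	Cardiac disorders
PT0022	Rash	HLGT0004	Epidermal and dermal conditions	SOC0009	Skin and subcutaneous tissue disorders
PT0020	Pruritus	HLGT0004	Epidermal and dermal conditions	SOC0009	Skin and subcutaneous tissue disorders
PT0028	Urticaria	HLGT0004	Epidermal and dermal conditions	SOC0009	Skin and subcutaneous tissue disorders
PT0002	Anaphylactic shock	HLGT0001	Allergic conditions	SOC0004	Immune system disorders
PT0008	Dyspnoea	HLGT0013	Respiratory disorders NEC	SOC0008	Respiratory, thoracic and mediastinal disorders
PT0021	Pyrexia	HLGT0006	General system disorders NEC	SOC0003	General disorders and administration site conditions
PT0012	Injection site pain	HLGT0006	General system disorders NEC	SOC0003	General disorders and administration site conditions
PT0003	Back pain	HLGT0008	Musculoskeletal and connective tissue disorders NEC	SOC0006	Musculoskeletal and connective tissue disorders
PT0001	Anaesthetic complication	HLGT0012	Procedural related injuries and complications NEC	SOC0005	Injury, poisoning and procedural complications
PT0013	Local anaesthetic systemic toxicity	HLGT0012	Procedural related injuries and complications NEC	SOC0005	Injury, poisoning and procedural complications
PT0013	Local anaesthetic systemic toxicity	HLGT0009	Neurological disorders NEC	SOC0007	Nervous system disorders
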