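# Demonstration disease lexicon for the five-drug demo knowledge base.
# Columns: concept_id <TAB> preferred_name <TAB> variant.
# The variant "diabetic neuopathy" is deliberate: review text is matched
# exactly as written, so the lexicon carries the misspelling that actually
# occurs in the demo review.
CD001	Dry cough	dry cough
CD002	Drug withdrawal syndrome	drug withdrawal syndrome
CD003	Opioid dependence	opioid dependence
CD003	Opioid dependence	opioid type drug dependence
CD004	Pain	pain
CD005	Diabetic neuropathy	diabetic neuropathy
CD005	Diabetic neuropathy	diabetic neuopathy
CD006	Fever	fever
CD007	Muscle spasm	spasm
CD007	Muscle spasm	muscle spasms
CD008	Acne	acne
CD009	Depression	depression
CD010	Chronic pain	chronic pain
CD011	Irritable bowel syndrome	irritable bowel syndrome
CD012	Insomnia	insomnia
CD013	Migraine	migraine
CD013	Migraine	migraines
CD014	Temporomandibular joint disorder	tmj
CD015	Attention-deficit hyperactivity disorder	adhd
CD016	Anxiety	anxiety
CD017	Hypertension	hypertension
CD017	Hypertension	low-renin hypertension
CD018	Hypokalemia	hypokalemia
CD019	Conn syndrome	conn syndrome
CD020	Hyperkalemia	hyperkalemia
CD021	Urticaria	urticaria
CD022	Amenorrhea	amenorrhea
CD023	Nausea	nausea
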