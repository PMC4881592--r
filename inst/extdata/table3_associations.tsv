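mirna	Colon	Prostate	Pancreatic	Lung	Breast	Bladder	Kidney	group
miR-124a	v	v	v	v	v	v		1
miR-9	v	v	v	v	v	v		1
miR-182	v	v	v	v	v	v		1
miR-135	v	v	v	v	v	v		1
miR-125b	v	v	v	v	v	v	v	2
miR-23b	v	v	v	v	v	v	v	2
miR-23a	v	v	v	v	v	v	v	2
miR-125a	v	v	v	v	v	v	v	2
miR-200b	v	v	v	v	v	v	v	2
miR-200c	v	v	v	v	v	v	v	2
miR-146	v			v		v	v	3
miR-199	v	v		v		v	v	4
miR-1	v		v					5
miR-30b	v		v	v		v		6
miR-200a	v		v	v		v		6
miR-30a	v		v	v		v		6
miR-30d	v		v	v		v		6
miR-30c	v		v	v		v		6
miR-30e	v		v	v		v		6
miR-137	v		v			v	v	7
miR-19a	v			v	v	v		8
miR-19b	v			v	v	v		8
miR-203	v		v	v	v	v		9
miR-155	v		v	v	v	v		9
miR-33	v			v	v	v	v	10
miR-219	v							11
miR-216	v							11
miR-223	v				v	v	v	12
miR-193	v				v			13
miR-29b		v			v	v	v	14
miR-29c		v			v	v	v	14
miR-29a		v			v	v	v	14
miR-206	v		v				v	15
miR-218		v	v		v	v		16
miR-128b		v	v		v	v		16
miR-128a		v	v		v	v		16
miR-34a	v			v	v		v	17
miR-34b	v			v	v		v	17
miR-34c	v			v	v		v	17
miR-194		v	v	v		v		18
miR-138		v	v	v				19
miR-96	v	v	v		v		v	20
miR-27b		v	v	v	v	v	v	21
miR-27a		v	v	v	v	v	v	21
miR-99a			v	v				22
miR-100			v	v				22
miR-107			v	v				22
miR-103			v	v				22
miR-99b			v	v				22
miR-181a			v		v	v	v	23
miR-181b			v		v	v	v	23
miR-204			v		v	v	v	23
miR-211			v		v	v	v	23
miR-181c			v		v	v	v	23
miR-24	v		v	v	v	v	v	24
miR-205			v			v		25
miR-215			v			v	v	26
miR-192			v			v	v	26
miR-21	v	v	v			v	v	27
miR-190			v		v	v		28
miR-26a			v		v	v		28
miR-144			v		v	v		28
miR-26b			v		v	v		28
miR-183	v	v	v		v	v		29
miR-22			v	v	v	v	v	30
miR-145	v		v		v	v	v	31
miR-140	v					v		32
miR-139	v				v	v		33
miR-143			v					34
miR-133a	v		v			v		35
miR-18				v				36
miR-101	v		v		v		v	37
miR-152				v	v	v		38
miR-148				v	v	v		38
miR-141				v	v	v		38
miR-302					v		v	39
miR-93					v		v	39
miR-16						v		40
miR-92						v		40
miR-142						v		40
miR106a						v		40
miR-17						v		40
miR-195						v		40
miR-20						v		40
miR-15a						v		40
miR-153						v		40
miR-106b						v		40
miR-25						v		40
miR-32						v		40
miR-199b							v	41
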