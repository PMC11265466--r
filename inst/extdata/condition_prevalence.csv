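rank,label,prevalence
1,"Dementia, Alzheimer's disease",33.4
2,"Ischemic Heart Disease",32.2
3,"Hypertensive disease",26.7
4,"Cerebrovascular disease",20.6
5,"Other circulatory diseases",17.1
6,"Heart failure",16.4
7,"Cardiac arrhythmia",15.1
8,"Kidney disease",14.5
9,"Diabetes",12.5
10,"Symptoms, signs, ill-defined conditions",11.1
11,"Chronic lower respiratory disease",11.0
12,"Musculoskeletal disease",10.4
13,"Other digestive diseases",7.9
14,"Infectious, parasitic diseases",6.7
15,"Other malignant neoplasms",5.9
16,"Other respiratory diseases",5.1
17,"Psychiatric and other mental disorders",4.6
18,"Influenza, pneumonia",4.4
19,"Breast cancer",3.3
20,"Colorectal cancer",3.1
21,"Lymph, blood cancer",3.0
22,"Other endocrine diseases",3.0
23,"Other neurological conditions",2.2
24,"Parkinson's disease",2.2
25,"Skin disease",2.0
26,"Lung, tracheal cancer",1.5
27,"Eye, ear disease",1.5
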