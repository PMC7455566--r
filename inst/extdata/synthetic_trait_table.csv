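"item_id","subscale","prevalence_asd","prevalence_control","prevalence_ratio","log_diagnosticity"
1,"social_skill",0.245960311115695,0.1,2.45960311115695,0.9
2,"social_skill",0.279174449278414,0.1,2.79174449278414,1.02666666666667
3,"social_skill",0.316873778441617,0.1,3.16873778441617,1.15333333333333
4,"social_skill",0.359663972556928,0.1,3.59663972556928,1.28
5,"social_skill",0.408232494943612,0.1,4.08232494943612,1.40666666666667
6,"social_skill",0.463359643010972,0.1,4.63359643010972,1.53333333333333
7,"social_skill",0.52593108444469,0.1,5.2593108444469,1.66
8,"social_skill",0.596952086262329,0.1,5.96952086262329,1.78666666666667
9,"social_skill",0.677563665340688,0.1,6.77563665340688,1.91333333333333
10,"social_skill",0.7690609198879,0.1,7.690609198879,2.04
11,"attention_switching",0.164872127070013,0.1,1.64872127070013,0.5
12,"attention_switching",0.176238264072866,0.1,1.76238264072866,0.566666666666667
13,"attention_switching",0.188387972396496,0.1,1.88387972396496,0.633333333333333
14,"attention_switching",0.201375270747048,0.1,2.01375270747048,0.7
15,"attention_switching",0.215257901831959,0.1,2.15257901831959,0.766666666666667
16,"attention_switching",0.230097589089283,0.1,2.30097589089283,0.833333333333333
17,"attention_switching",0.245960311115695,0.1,2.45960311115695,0.9
18,"attention_switching",0.262916595013326,0.1,2.62916595013326,0.966666666666667
19,"attention_switching",0.281041829959655,0.1,2.81041829959655,1.03333333333333
20,"attention_switching",0.300416602394643,0.1,3.00416602394643,1.1
21,"attention_to_detail",0.0740818220681718,0.1,0.740818220681718,-0.3
22,"attention_to_detail",0.0791889566336782,0.1,0.791889566336782,-0.233333333333333
23,"attention_to_detail",0.0846481724890614,0.1,0.846481724890614,-0.166666666666667
24,"attention_to_detail",0.090483741803596,0.1,0.90483741803596,-0.1
25,"attention_to_detail",0.0967216100482006,0.1,0.967216100482006,-0.0333333333333333
26,"attention_to_detail",0.103389511351357,0.1,1.03389511351357,0.0333333333333333
27,"attention_to_detail",0.110517091807565,0.1,1.10517091807565,0.1
28,"attention_to_detail",0.118136041286565,0.1,1.18136041286565,0.166666666666667
29,"attention_to_detail",0.12628023432938,0.1,1.2628023432938,0.233333333333333
30,"attention_to_detail",0.1349858807576,0.1,1.349858807576,0.3
31,"communication",0.149182469764127,0.1,1.49182469764127,0.4
32,"communication",0.159466975822832,0.1,1.59466975822832,0.466666666666667
33,"communication",0.170460486532275,0.1,1.70460486532275,0.533333333333333
34,"communication",0.182211880039051,0.1,1.82211880039051,0.6
35,"communication",0.194773404105468,0.1,1.94773404105468,0.666666666666667
36,"communication",0.208200908407846,0.1,2.08200908407846,0.733333333333333
37,"communication",0.222554092849247,0.1,2.22554092849247,0.8
38,"communication",0.237896772990663,0.1,2.37896772990663,0.866666666666667
39,"communication",0.254297163780795,0.1,2.54297163780795,0.933333333333333
40,"communication",0.271828182845905,0.1,2.71828182845905,1
41,"imagination",0.1349858807576,0.1,1.349858807576,0.3
42,"imagination",0.144291686665534,0.1,1.44291686665534,0.366666666666667
43,"imagination",0.154239026511017,0.1,1.54239026511017,0.433333333333333
44,"imagination",0.164872127070013,0.1,1.64872127070013,0.5
45,"imagination",0.176238264072866,0.1,1.76238264072866,0.566666666666667
46,"imagination",0.188387972396496,0.1,1.88387972396496,0.633333333333333
47,"imagination",0.201375270747048,0.1,2.01375270747048,0.7
48,"imagination",0.215257901831959,0.1,2.15257901831959,0.766666666666667
49,"imagination",0.230097589089283,0.1,2.30097589089283,0.833333333333333
50,"imagination",0.245960311115695,0.1,2.45960311115695,0.9
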