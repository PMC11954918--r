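piece_id,piece,performer,composer,version,mean_bpm,mean_sones,is_source
gavotte,"Gavotte Op. 12 No. 2",Prokofiev,Prokofiev,V1,110.58,15.05,TRUE
gavotte,"Gavotte Op. 12 No. 2",Prokofiev,Prokofiev,V2,110.68,20.54,FALSE
gavotte,"Gavotte Op. 12 No. 2",Prokofiev,Prokofiev,V3,199.05,17.39,FALSE
gavotte,"Gavotte Op. 12 No. 2",Prokofiev,Prokofiev,V4,199.02,23.84,FALSE
serenade,"Standchen (Serenade)",Bauer,Schubert-Liszt,V1,54.75,12.00,TRUE
serenade,"Standchen (Serenade)",Bauer,Schubert-Liszt,V2,54.75,18.08,FALSE
serenade,"Standchen (Serenade)",Bauer,Schubert-Liszt,V3,120.26,14.33,FALSE
serenade,"Standchen (Serenade)",Bauer,Schubert-Liszt,V4,120.20,21.30,FALSE
mozart_k576,"Piano Sonata No. 18 in D major K.576 (Adagio)",Landowska,Mozart,V1,46.45,12.14,TRUE
mozart_k576,"Piano Sonata No. 18 in D major K.576 (Adagio)",Landowska,Mozart,V2,46.45,16.36,FALSE
mozart_k576,"Piano Sonata No. 18 in D major K.576 (Adagio)",Landowska,Mozart,V3,92.62,14.23,FALSE
mozart_k576,"Piano Sonata No. 18 in D major K.576 (Adagio)",Landowska,Mozart,V4,92.86,20.12,FALSE
sunken_cathedral,"La Cathedrale Engloutie (Sunken Cathedral)",Debussy,Debussy,V1,38.66,7.00,FALSE
sunken_cathedral,"La Cathedrale Engloutie (Sunken Cathedral)",Debussy,Debussy,V2,38.71,12.27,TRUE
sunken_cathedral,"La Cathedrale Engloutie (Sunken Cathedral)",Debussy,Debussy,V3,134.97,9.60,FALSE
sunken_cathedral,"La Cathedrale Engloutie (Sunken Cathedral)",Debussy,Debussy,V4,96.64,15.79,FALSE
nocturne,"Nocturne in F-sharp minor Op. 48 No. 2",Hofmann,Chopin,V1,68.85,13.49,TRUE
nocturne,"Nocturne in F-sharp minor Op. 48 No. 2",Hofmann,Chopin,V3,172.10,16.46,FALSE
berceuse,"Berceuse Op. 57 D-flat major",Reisenaur,Chopin,V1,27.44,7.85,TRUE
berceuse,"Berceuse Op. 57 D-flat major",Reisenaur,Chopin,V2,27.42,17.37,FALSE
berceuse,"Berceuse Op. 57 D-flat major",Reisenaur,Chopin,V3,54.85,9.41,FALSE
berceuse,"Berceuse Op. 57 D-flat major",Reisenaur,Chopin,V4,54.85,19.50,FALSE
moonlight,"Sonata No. 14 in C-sharp minor Op. 27 No. 2 (Moonlight)",Lhevinne,Beethoven,V1,45.62,8.92,TRUE
moonlight,"Sonata No. 14 in C-sharp minor Op. 27 No. 2 (Moonlight)",Lhevinne,Beethoven,V2,45.53,13.60,FALSE
moonlight,"Sonata No. 14 in C-sharp minor Op. 27 No. 2 (Moonlight)",Lhevinne,Beethoven,V3,172.88,12.96,FALSE
moonlight,"Sonata No. 14 in C-sharp minor Op. 27 No. 2 (Moonlight)",Lhevinne,Beethoven,V4,172.83,19.45,FALSE
ave_maria,"Ave Maria (Meditation sur le Premier Prelude de Piano de S. Bach)",Lemer,Bach-Gounod,V1,60.22,9.52,TRUE
ave_maria,"Ave Maria (Meditation sur le Premier Prelude de Piano de S. Bach)",Lemer,Bach-Gounod,V2,60.08,14.62,FALSE
ave_maria,"Ave Maria (Meditation sur le Premier Prelude de Piano de S. Bach)",Lemer,Bach-Gounod,V3,150.06,11.77,FALSE
ave_maria,"Ave Maria (Meditation sur le Premier Prelude de Piano de S. Bach)",Lemer,Bach-Gounod,V4,150.09,16.53,FALSE
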